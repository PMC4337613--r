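#' Segregate a localization stream into time windows
#'
#' Partitions frames `1..n_frames` into contiguous, non-overlapping
#' windows covering the whole acquisition. Windows are equal in frames;
#' any remainder goes to the earliest windows (e.g. 10 frames in 3 windows
#' gives sizes 4, 3, 3). Every localization is assigned to exactly one
#' window by its frame stamp.
#'
#' @param locs a [localization_table()].
#' @param n_windows number of windows (>= 2), or NULL if `window_frames`
#'   is given.
#' @param window_frames alternatively, the number of frames per window.
#' @param n_frames total frames; defaults to `max(locs$frame)`.
#' @return an object of class `time_window_set`: list with
#'   `frame_start`, `frame_end` (inclusive integer ranges) and `windows`
#'   (list of per-window localization tables).
#' @export
split_time_windows <- function(locs, n_windows = NULL, window_frames = NULL,
                               n_frames = NULL) {
  if (is.null(n_frames)) n_frames <- max(locs$frame)
  n_frames <- as.integer(n_frames)
  if (is.null(n_windows) && is.null(window_frames))
    stop_invalid("give either 'n_windows' or 'window_frames'")
  if (is.null(n_windows)) {
    if (window_frames < 1) stop_invalid("'window_frames' must be >= 1")
    n_windows <- ceiling(n_frames / window_frames)
    sizes <- rep(as.integer(window_frames), n_windows)
    sizes[n_windows] <- n_frames - sum(sizes[-n_windows])
  } else {
    n_windows <- as.integer(n_windows)
    if (n_windows < 2) stop_invalid("'n_windows' must be >= 2")
    if (n_windows > n_frames)
      stop_invalid("more windows than frames")
    base <- n_frames %/% n_windows
    rem <- n_frames %% n_windows
    sizes <- rep(base, n_windows) + c(rep(1L, rem), rep(0L, n_windows - rem))
  }
  frame_end <- cumsum(sizes)
  frame_start <- c(1L, utils::head(frame_end, -1L) + 1L)
  idx <- findInterval(locs$frame, frame_start)
  windows <- lapply(seq_len(n_windows), function(w) {
    sub <- as.data.frame(locs)[idx == w, , drop = FALSE]
    rownames(sub) <- NULL
    class(sub) <- c("localization_table", "data.frame")
    sub
  })
  structure(list(frame_start = as.integer(frame_start),
                 frame_end = as.integer(frame_end),
                 windows = windows),
            class = "time_window_set")
}

#' @export
print.time_window_set <- function(x, ...) {
  cat(sprintf("<time_window_set> %d windows; frames %s; counts %s\n",
              length(x$windows),
              paste(sprintf("[%d,%d]", x$frame_start, x$frame_end),
                    collapse = " "),
              paste(vapply(x$windows, nrow, integer(1)), collapse = ", ")))
  invisible(x)
}

window_profile <- function(locs, trace, bin_size_nm, max_lateral_nm) {
  proj <- project_onto_trace(locs, trace, max_lateral_nm)
  density_profile(proj$s, bin_size_nm, range_nm = c(0, trace_length(trace)))
}

#' Per-window dominant periods of a live series
#'
#' Computes a [dominant_period()] spectrum for each time window's axial
#' density profile (shared bin grid over the whole trace). For a stable
#' lattice the per-window periods agree; a pure lattice translation leaves
#' them unchanged (the power spectrum is translation invariant). Empty or
#' degenerate windows yield a flagged NA result rather than an error.
#'
#' @param tws a [split_time_windows()] result.
#' @param trace a [neurite_trace()].
#' @param bin_size_nm profile bin width (default 10).
#' @param band_nm period search band (default c(100, 400)).
#' @param max_lateral_nm projection acceptance radius.
#' @return a data frame with `window`, `dominant_period_nm`,
#'   `low_confidence`, `n_locs`; the per-window `spectrum_result`s are in
#'   attribute `spectra`.
#' @export
window_spectra <- function(tws, trace, bin_size_nm = 10,
                           band_nm = c(100, 400), max_lateral_nm = 400) {
  stopifnot(inherits(tws, "time_window_set"))
  spectra <- lapply(tws$windows, function(w) {
    tryCatch({
      prof <- window_profile(w, trace, bin_size_nm, max_lateral_nm)
      dominant_period(prof, band_nm)
    }, mpskel_error = function(e) NULL)
  })
  out <- data.frame(
    window = seq_along(spectra),
    dominant_period_nm = vapply(spectra, function(sp)
      if (is.null(sp)) NA_real_ else sp$dominant_period_nm, numeric(1)),
    low_confidence = vapply(spectra, function(sp)
      if (is.null(sp)) TRUE else sp$low_confidence, logical(1)),
    n_locs = vapply(tws$windows, nrow, integer(1))
  )
  attr(out, "spectra") <- spectra
  out
}

#' Cross-correlation between two time windows' density profiles
#'
#' Pearson-normalized cross-correlation of the two windows' mean-subtracted
#' axial profiles on a common bin grid:
#' `cc(l) = sum_s (rho1(s) - m1)(rho2(s + l) - m2) / (N * sd1 * sd2)`,
#' with the fixed-N denominator matching [autocorrelation()], so the
#' window-vs-itself case reduces exactly to the autocorrelation. The phase
#' shift is the lag of the maximum over `[-max_lag, +max_lag]` (smallest
#' `|lag|` on ties); a positive shift means the second window's pattern
#' sits at larger arc length.
#'
#' @param window1,window2 localization tables (e.g. elements of
#'   `tws$windows`); `window1` is the reference.
#' @param trace a [neurite_trace()].
#' @param bin_size_nm shared bin width (default 10).
#' @param max_lag_nm lag range (default 1000).
#' @param max_lateral_nm projection acceptance radius.
#' @return an object of class `crosscorr_result`: list with `lags_nm`
#'   (symmetric about 0), `cc`, `peak_lag_nm`, `bin_size_nm`.
#' @export
window_cross_correlation <- function(window1, window2, trace,
                                     bin_size_nm = 10, max_lag_nm = 1000,
                                     max_lateral_nm = 400) {
  if (nrow(window1) == 0L || nrow(window2) == 0L)
    stop_invalid("both windows must contain localizations")
  p1 <- window_profile(window1, trace, bin_size_nm, max_lateral_nm)
  p2 <- window_profile(window2, trace, bin_size_nm, max_lateral_nm)
  N <- length(p1$counts)
  max_lag_bins <- round(max_lag_nm / bin_size_nm)
  if (N < 2 * max_lag_bins)
    stop_invalid("profiles must span at least twice the maximum lag")
  c1 <- center_profile(p1$counts, "reference window profile")
  c2 <- center_profile(p2$counts, "comparison window profile")
  lags <- (-max_lag_bins):max_lag_bins
  cc <- vapply(lags, function(l) {
    if (l >= 0) {
      i <- seq_len(N - l)
      sum(c1$d[i] * c2$d[i + l])
    } else {
      i <- seq_len(N + l)
      sum(c1$d[i - l] * c2$d[i])
    }
  }, numeric(1)) / (N * sqrt(c1$var) * sqrt(c2$var))
  # peak: maximum cc; ties broken toward the smallest |lag|
  ord <- order(-cc, abs(lags), lags)
  peak_lag <- lags[ord[1]] * bin_size_nm
  structure(list(lags_nm = lags * bin_size_nm, cc = cc,
                 peak_lag_nm = peak_lag, bin_size_nm = bin_size_nm),
            class = "crosscorr_result")
}

#' @export
print.crosscorr_result <- function(x, ...) {
  cat(sprintf("<crosscorr_result> lags +/-%g nm; peak lag %g nm (cc %.3f)\n",
              max(x$lags_nm), x$peak_lag_nm, max(x$cc)))
  invisible(x)
}

#' Phase-shift table of a live series
#'
#' Convenience wrapper reproducing the live-cell stability analysis:
#' splits the stream into `n_windows`, then reports the cross-correlation
#' phase shift of every later window against the first.
#'
#' @param locs a live-series [localization_table()].
#' @param trace a [neurite_trace()].
#' @param n_windows number of time windows (default 4).
#' @param ... passed to [window_cross_correlation()].
#' @return a data frame with `window`, `peak_lag_nm`, `n_locs`.
#' @export
phase_shift_table <- function(locs, trace, n_windows = 4, ...) {
  tws <- split_time_windows(locs, n_windows = n_windows)
  ref <- tws$windows[[1]]
  rows <- lapply(seq_along(tws$windows)[-1], function(w) {
    cc <- window_cross_correlation(ref, tws$windows[[w]], trace, ...)
    data.frame(window = w, peak_lag_nm = cc$peak_lag_nm,
               n_locs = nrow(tws$windows[[w]]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
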