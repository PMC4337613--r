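#' Synthetic developmental course of lattice propagation
#'
#' Simulates cohorts of axons whose ring occupancy decays toward the
#' distal end with cohort-specific decay lengths — short decay standing in
#' for young neurons where the lattice occupies only the proximal axon,
#' long/infinite decay for mature neurons where it spans the whole axon —
#' and scores periodicity per axonal segment with
#' [periodicity_vs_distance()]. The output is the synthetic analog of an
#' amplitude-vs-distance developmental summary.
#'
#' @param decay_lengths_um named or unnamed vector of occupancy e-folding
#'   lengths per cohort (default c(5, 15, Inf) um, young to mature).
#' @param n_neurons axons per cohort (default 5).
#' @param length_um axon length (default 30).
#' @param segment_length_um scoring segment length (default 5).
#' @param seed global seed; per-axon seeds are derived with
#'   [derive_seed()].
#' @param out_dir optional directory; if given, the summary is written to
#'   `development_course.csv` with a provenance sidecar.
#' @return a data frame with `cohort`, `decay_length_um`, `segment`,
#'   `center_um`, `mean_amplitude`, `sd_amplitude`, `mean_n_locs`.
#' @export
run_development_course <- function(decay_lengths_um = c(5, 15, Inf),
                                   n_neurons = 5, length_um = 30,
                                   segment_length_um = 5, seed = 1L,
                                   out_dir = NULL) {
  if (n_neurons < 1) stop_invalid("'n_neurons' must be >= 1")
  trace <- make_trace(length_um)
  cohort_names <- names(decay_lengths_um)
  if (is.null(cohort_names))
    cohort_names <- paste0("cohort", seq_along(decay_lengths_um))
  rows <- list()
  counter <- 0L
  for (ci in seq_along(decay_lengths_um)) {
    per_axon <- lapply(seq_len(n_neurons), function(j) {
      counter <<- counter + 1L
      cfg <- lattice_config(density_decay_length_um = unname(decay_lengths_um[ci]),
                            seed = derive_seed(seed, counter))
      locs <- simulate_lattice(trace, cfg)
      periodicity_vs_distance(locs, trace, segment_length_um)
    })
    n_seg <- nrow(per_axon[[1]])
    amp <- sapply(per_axon, function(x) x$amplitude)
    nlc <- sapply(per_axon, function(x) x$n_locs)
    amp <- matrix(amp, nrow = n_seg)
    nlc <- matrix(nlc, nrow = n_seg)
    rows[[ci]] <- data.frame(
      cohort = cohort_names[ci],
      decay_length_um = unname(decay_lengths_um[ci]),
      segment = per_axon[[1]]$segment,
      center_um = per_axon[[1]]$center_um,
      mean_amplitude = rowMeans(amp, na.rm = TRUE),
      sd_amplitude = if (n_neurons > 1) apply(amp, 1, stats::sd, na.rm = TRUE)
                     else NA_real_,
      mean_n_locs = rowMeans(nlc)
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    path <- file.path(out_dir, "development_course.csv")
    utils::write.csv(out, path, row.names = FALSE)
    write_sidecar(path, list(kind = "development_course", seed = seed,
                             n_neurons = n_neurons,
                             decay_lengths_um = unname(decay_lengths_um)))
  }
  out
}

#' End-to-end demonstration run on synthetic data
#'
#' Generates synthetic fixtures for every analysis stage and runs the full
#' pipeline: lattice vs irregular periodicity (dominant period and
#' autocorrelation amplitude), subsampling robustness, live-cell stability
#' (per-window periods and phase shifts, static and drifting), FRAP
#' recovery fractions and fit for both expression presets, and
#' axon/dendrite polarity ratios for both genotype presets. All randomness
#' derives from the single seed.
#'
#' @param seed global integer seed.
#' @param out_dir optional directory for `report.json` and CSV artifacts.
#' @param n_subsample_reps replicates for the subsampling stage
#'   (default 25; the dedicated analysis uses more).
#' @return the report as a nested list (invisibly written to JSON when
#'   `out_dir` is given).
#' @export
run_full_demo <- function(seed = 1L, out_dir = NULL, n_subsample_reps = 25) {
  trace <- make_trace(30)
  L <- trace_length(trace)

  # -- fixed-cell periodicity: lattice vs irregular -------------------------
  lat <- simulate_lattice(trace, lattice_config(seed = derive_seed(seed, 1)))
  irr <- simulate_irregular(trace, lattice_config(seed = derive_seed(seed, 2)))
  analyze <- function(locs) {
    proj <- project_onto_trace(locs, trace)
    prof <- density_profile(proj$s, 10, range_nm = c(0, L))
    ac <- autocorrelation(prof)
    sp <- dominant_period(prof)
    list(n_locs = nrow(locs), n_projected = nrow(proj),
         amplitude = ac$amplitude, first_peak_lag_nm = ac$first_peak_lag_nm,
         dominant_period_nm = sp$dominant_period_nm,
         low_confidence = sp$low_confidence)
  }
  periodicity <- list(lattice = analyze(lat), irregular = analyze(irr))

  # -- subsampling robustness ----------------------------------------------
  n <- nrow(lat)
  subsamp <- subsample_robustness(
    lat, trace, target_counts = c(n, round(n / 2), round(n / 4)),
    n_reps = n_subsample_reps, seed = derive_seed(seed, 3))

  # -- live-cell stability --------------------------------------------------
  live_static <- simulate_live_series(trace, live_series_config(
    n_frames = 24000, frame_rate_hz = 60, phase_drift_nm_per_s = 0,
    lattice = lattice_config(seed = derive_seed(seed, 4))))
  live_drift <- simulate_live_series(trace, live_series_config(
    n_frames = 24000, frame_rate_hz = 60, phase_drift_nm_per_s = 1,
    lattice = lattice_config(seed = derive_seed(seed, 5))))
  tws <- split_time_windows(live_static, n_windows = 4)
  spectra <- window_spectra(tws, trace)
  live <- list(
    static_periods_nm = spectra$dominant_period_nm,
    static_phase_shifts = phase_shift_table(live_static, trace),
    drift_phase_shifts = phase_shift_table(live_drift, trace)
  )

  # -- FRAP -----------------------------------------------------------------
  frap <- lapply(c(high = "high", low = "low"), function(which) {
    tr <- simulate_frap(frap_preset(which, acq_bleach_rate_per_s = 0.001,
                                    seed = derive_seed(seed, 6)))
    out <- list(recovery_fraction_300s = recovery_fraction(tr, 300),
                recovery_fraction_600s = recovery_fraction(tr, 600))
    if (which == "high") {
      fit <- fit_recovery(tr)
      out$mobile_fraction_est <- fit$mobile_fraction_est
      out$halftime_est_s <- fit$halftime_est_s
    }
    out
  })

  # -- polarity -------------------------------------------------------------
  polarity <- lapply(c(`wild-type` = "wild-type",
                       `ankyrin-b-ko` = "ankyrin-b-ko"), function(which) {
    sim <- simulate_polarity_image(polarity_preset(which,
                                                   seed = derive_seed(seed, 7)))
    ir <- intensity_ratio(sim$image, sim$masks)
    list(ratio = ir$ratio, relative_dendrite = unname(ir$relative["dendrite"]))
  })

  report <- list(
    seed = seed,
    periodicity = periodicity,
    subsampling = subsamp,
    live = live,
    frap = frap,
    polarity = polarity
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "columns")
    utils::write.csv(subsamp, file.path(out_dir, "subsampling.csv"),
                     row.names = FALSE)
  }
  report
}
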