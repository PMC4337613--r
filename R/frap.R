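#' FRAP traces
#'
#' Bleached-ROI and unbleached-reference intensity time series from a FRAP
#' (fluorescence recovery after photobleaching) experiment. The reference
#' region calibrates acquisition photobleaching.
#'
#' @param df data frame with numeric columns `t_s` (strictly increasing),
#'   `roi` and `reference` (both >= 0).
#' @param t_bleach_s time of the bleach event; at least 2 samples must
#'   precede it.
#' @return a data frame of class `frap_trace` with attribute `t_bleach_s`.
#' @export
frap_trace <- function(df, t_bleach_s = 0) {
  df <- as.data.frame(df)
  for (col in c("t_s", "roi", "reference"))
    if (!col %in% names(df))
      stop_format(sprintf("FRAP trace is missing column '%s'", col))
  if (any(diff(df$t_s) <= 0))
    stop_invalid("'t_s' must be strictly increasing")
  if (any(df$roi < 0) || any(df$reference < 0))
    stop_invalid("intensities must be >= 0")
  if (sum(df$t_s < t_bleach_s) < 2)
    stop_invalid("need at least 2 pre-bleach samples")
  attr(df, "t_bleach_s") <- t_bleach_s
  class(df) <- c("frap_trace", "data.frame")
  df
}

pre_bleach_idx <- function(trace) {
  which(trace$t_s < attr(trace, "t_bleach_s"))
}

#' Correct a FRAP trace for acquisition photobleaching
#'
#' Uses the unbleached reference region to calibrate photobleaching over
#' the recording: `corrected(t) = roi(t) * mean(reference pre-bleach) /
#' reference(t)` (multiplicative ratio correction). With a constant
#' reference this is the identity on `roi`.
#'
#' @param trace a [frap_trace()].
#' @return the trace with an added `corrected` column.
#' @export
bleach_correct <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  if (any(trace$reference <= 0))
    stop_degenerate("reference trace has non-positive values; cannot correct")
  ref0 <- mean(trace$reference[pre_bleach_idx(trace)])
  trace$corrected <- trace$roi * ref0 / trace$reference
  trace
}

#' Fluorescence recovery fraction at given times
#'
#' The recovery fraction is the bleach-corrected ROI intensity at time `t`
#' relative to the mean corrected pre-bleach intensity:
#' `R(t) = corrected(t) / mean(corrected pre-bleach)`. Values at requested
#' times are linearly interpolated between samples.
#'
#' @param trace a [frap_trace()]; bleach-corrected automatically if the
#'   `corrected` column is absent.
#' @param times_s times (same clock as `t_s`, i.e. seconds relative to the
#'   bleach for simulated traces) at which to report; must lie after the
#'   bleach and within the record.
#' @return numeric vector of recovery fractions, one per requested time.
#' @export
recovery_fraction <- function(trace, times_s) {
  stopifnot(inherits(trace, "frap_trace"))
  if (!"corrected" %in% names(trace)) trace <- bleach_correct(trace)
  tb <- attr(trace, "t_bleach_s")
  if (any(times_s < tb) || any(times_s > max(trace$t_s)))
    stop_invalid("requested times must lie between the bleach and the end of the record")
  baseline <- mean(trace$corrected[pre_bleach_idx(trace)])
  r <- trace$corrected / baseline
  stats::approx(trace$t_s, r, xout = times_s, method = "linear")$y
}

#' Fit a single-exponential recovery model to a FRAP trace
#'
#' Least-squares fit of `R(t) = R0 + A * (1 - 2^(-(t - t_bleach) / tau))`
#' to the post-bleach recovery-fraction series (half-time
#' parameterization). Since the post-bleach floor `R0` estimates
#' `1 - bleach_depth`, the mobile fraction is recovered as
#' `A / (1 - R0)`.
#'
#' @param trace a [frap_trace()] with >= 10 post-bleach samples.
#' @return a list with `mobile_fraction_est`, `halftime_est_s`, `R0_est`,
#'   `amplitude_est`, `rms_residual`.
#' @export
fit_recovery <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  if (!"corrected" %in% names(trace)) trace <- bleach_correct(trace)
  tb <- attr(trace, "t_bleach_s")
  post <- trace$t_s >= tb
  if (sum(post) < 10)
    stop_invalid("need at least 10 post-bleach samples to fit")
  baseline <- mean(trace$corrected[pre_bleach_idx(trace)])
  df <- data.frame(t = trace$t_s[post] - tb,
                   r = trace$corrected[post] / baseline)
  r0_start <- df$r[1]
  a_start <- max(max(df$r) - r0_start, 0.01)
  span <- max(df$t)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      r ~ R0 + A * (1 - 2^(-t / tau)), data = df,
      start = list(R0 = r0_start, A = a_start, tau = span / 5),
      lower = c(R0 = 0, A = 0, tau = 1e-6),
      upper = c(R0 = 2, A = 2, tau = 100 * span),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) stop_fit(paste("recovery fit failed:",
                                       conditionMessage(e)))
  )
  est <- stats::coef(fit)
  denom <- 1 - est[["R0"]]
  list(
    mobile_fraction_est = if (denom > 1e-6) unname(est[["A"]] / denom) else NA_real_,
    halftime_est_s = unname(est[["tau"]]),
    R0_est = unname(est[["R0"]]),
    amplitude_est = unname(est[["A"]]),
    rms_residual = sqrt(mean(stats::residuals(fit)^2))
  )
}
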