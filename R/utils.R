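#' @keywords internal
"_PACKAGE"

# Typed condition helpers: analysis pipelines need to distinguish bad
# arguments from degenerate data (e.g. zero-variance profiles) so batch
# runs can skip-and-log rather than abort.
stop_invalid <- function(msg) {
  stop(errorCondition(msg, class = c("mpskel_invalid_argument", "mpskel_error")))
}

stop_degenerate <- function(msg) {
  stop(errorCondition(msg, class = c("mpskel_degenerate_input", "mpskel_error")))
}

stop_format <- function(msg) {
  stop(errorCondition(msg, class = c("mpskel_format_error", "mpskel_error")))
}

stop_fit <- function(msg) {
  stop(errorCondition(msg, class = c("mpskel_fit_error", "mpskel_error")))
}

# Run code under a fixed seed without clobbering the caller's RNG stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Derive a per-stage child seed from a global seed
#'
#' Counter-based derivation so that adding a pipeline stage never perturbs
#' the random stream of earlier stages. The result always fits in a 32-bit
#' integer.
#'
#' @param seed global integer seed.
#' @param k stage counter (non-negative integer).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, k) {
  s <- abs(as.numeric(seed)) %% 1e6
  as.integer((s * 1021 + as.numeric(k) * 7919 + 1) %% .Machine$integer.max)
}

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  x <- unname(x)
  # +Inf is a legal value for scale parameters (e.g. no distal decay)
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (!is.finite(x) && !(is.infinite(x) && x > 0)))
    stop_invalid(sprintf("'%s' must be a single number", name))
  if (positive && x <= 0) stop_invalid(sprintf("'%s' must be > 0", name))
  if (nonneg && x < 0) stop_invalid(sprintf("'%s' must be >= 0", name))
  invisible(x)
}
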