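#' Localization tables
#'
#' The pipeline's universal currency: one row per detected molecule with
#' coordinates in nm and a camera-frame stamp. Ground-truth tables from the
#' simulators carry a `truth_ring` column (ring index, -1 = background or
#' unknown).
#'
#' @param df a data frame with numeric columns `x_nm`, `y_nm` and `frame`
#'   (integer >= 1); `z_nm`, `id` and `truth_ring` are filled in if absent.
#' @return a data frame of class `localization_table` with columns
#'   `id, frame, x_nm, y_nm, z_nm, truth_ring` first; any extra columns are
#'   preserved after them.
#' @export
localization_table <- function(df) {
  df <- as.data.frame(df)
  for (col in c("x_nm", "y_nm", "frame")) {
    if (!col %in% names(df))
      stop_format(sprintf("localization table is missing mandatory column '%s'", col))
  }
  if (!"z_nm" %in% names(df)) df$z_nm <- rep(0, nrow(df))
  if (!"id" %in% names(df)) df$id <- seq_len(nrow(df))
  if (!"truth_ring" %in% names(df)) df$truth_ring <- rep(-1L, nrow(df))
  num_cols <- c("x_nm", "y_nm", "z_nm")
  for (col in num_cols) {
    if (!is.numeric(df[[col]]) || any(!is.finite(df[[col]])))
      stop_format(sprintf("column '%s' must be finite numeric", col))
  }
  if (!is.numeric(df$frame) || any(df$frame < 1))
    stop_invalid("'frame' must be numeric and >= 1")
  df$frame <- as.integer(df$frame)
  df$id <- as.integer(df$id)
  df$truth_ring <- as.integer(df$truth_ring)
  canon <- c("id", "frame", "x_nm", "y_nm", "z_nm", "truth_ring")
  extra <- setdiff(names(df), canon)
  df <- df[, c(canon, extra), drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("localization_table", "data.frame")
  df
}

empty_localization_table <- function() {
  localization_table(data.frame(x_nm = numeric(0), y_nm = numeric(0),
                                z_nm = numeric(0), frame = integer(0)))
}
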