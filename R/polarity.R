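#' Compartment masks for polarity analysis
#'
#' Boolean pixel masks delineating the axon, dendrite and (optionally)
#' background compartments of an intensity image. Masks must be pairwise
#' disjoint and non-empty.
#'
#' @param axon,dendrite logical matrices of equal dimensions.
#' @param background optional logical matrix (same dimensions).
#' @return a list of class `compartment_masks`.
#' @export
compartment_masks <- function(axon, dendrite, background = NULL) {
  if (!is.logical(axon) || !is.logical(dendrite))
    stop_invalid("masks must be logical matrices")
  if (!identical(dim(axon), dim(dendrite)))
    stop_invalid("masks must have identical dimensions")
  if (!any(axon) || !any(dendrite))
    stop_invalid("axon and dendrite masks must be non-empty")
  if (any(axon & dendrite))
    stop_invalid("axon and dendrite masks must be disjoint")
  if (!is.null(background)) {
    if (!identical(dim(background), dim(axon)))
      stop_invalid("background mask dimensions must match")
    if (any(background & (axon | dendrite)))
      stop_invalid("background mask must be disjoint from the compartments")
    if (!any(background)) background <- NULL
  }
  structure(list(axon = axon, dendrite = dendrite, background = background),
            class = "compartment_masks")
}

#' Mean pixel intensity under a mask
#'
#' @param image an `mps_image` (or bare numeric matrix).
#' @param mask logical matrix matching the image dimensions.
#' @return arithmetic mean of the masked pixels.
#' @export
masked_mean <- function(image, mask) {
  px <- if (inherits(image, "mps_image")) image$pixels else as.matrix(image)
  if (!is.logical(mask) || !identical(dim(mask), dim(px)))
    stop_invalid("mask must be a logical matrix matching the image")
  if (!any(mask)) stop_invalid("mask is empty")
  mean(px[mask])
}

#' Axon/dendrite intensity ratio
#'
#' The polarity statistic: mean axonal intensity over mean dendritic
#' intensity, optionally after subtracting the background-mask mean from
#' both (clipped at 0). Also returns the normalized pair
#' `(axon = 1, dendrite = 1/ratio)` — the "relative fluorescence
#' intensity" presentation with the axon set to 1.
#'
#' @param image an `mps_image` or numeric matrix.
#' @param masks a [compartment_masks()].
#' @param background_subtract subtract the background mean first? Default:
#'   TRUE when a background mask is present, FALSE otherwise.
#' @return a list with `ratio`, `relative` (named pair), `axon_mean`,
#'   `dendrite_mean`, `background_mean`, `background_subtracted`.
#' @export
intensity_ratio <- function(image, masks, background_subtract = NULL) {
  stopifnot(inherits(masks, "compartment_masks"))
  has_bg <- !is.null(masks$background)
  if (is.null(background_subtract)) background_subtract <- has_bg
  if (background_subtract && !has_bg)
    stop_invalid("background subtraction requested but no background mask given")
  a <- masked_mean(image, masks$axon)
  d <- masked_mean(image, masks$dendrite)
  bg <- if (has_bg) masked_mean(image, masks$background) else NA_real_
  if (background_subtract) {
    a <- max(a - bg, 0)
    d <- max(d - bg, 0)
  }
  if (d <= 0)
    stop_degenerate("dendrite mean is <= 0 after background subtraction")
  ratio <- a / d
  list(ratio = ratio,
       relative = c(axon = 1, dendrite = 1 / ratio),
       axon_mean = a, dendrite_mean = d, background_mean = bg,
       background_subtracted = background_subtract)
}
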