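#' Images with physical pixel size
#'
#' @param pixels numeric matrix (row-major image; row i, column j). Pixel
#'   (i, j) spans `[x0 + (j-1)*p, x0 + j*p) x [y0 + (i-1)*p, y0 + i*p)` nm
#'   (half-open), where `p` is the pixel size and `(x0, y0)` the origin.
#' @param pixel_size_nm pixel pitch in nm (> 0).
#' @param origin_nm c(x0, y0) offset of the image in nm (default c(0, 0)).
#' @return an object of class `mps_image`.
#' @export
mps_image <- function(pixels, pixel_size_nm, origin_nm = c(0, 0)) {
  pixels <- as.matrix(pixels)
  check_scalar(pixel_size_nm, "pixel_size_nm", positive = TRUE)
  if (any(!is.finite(pixels))) stop_invalid("image pixels must be finite")
  structure(list(pixels = pixels, pixel_size_nm = pixel_size_nm,
                 origin_nm = as.numeric(origin_nm[1:2])),
            class = "mps_image")
}

#' @export
print.mps_image <- function(x, ...) {
  cat(sprintf("<mps_image> %d x %d px @ %g nm/px\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_nm))
  invisible(x)
}

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(path, extra = list()) {
  meta <- c(list(software = "mpskel",
                 version = as.character(utils::packageVersion("mpskel"))),
            extra)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(sidecar_path(path))
}

#' Read a localization table from CSV
#'
#' Two dialects are supported and detected by header match only:
#' `"native"` (`id,frame,x_nm,y_nm,z_nm,truth_ring`) and
#' `"thunderstorm"` (columns `"x [nm]"`, `"y [nm]"`, `"z [nm]"`,
#' `"frame"`). Unknown columns are preserved. A missing z column is
#' treated as 0 with a warning.
#'
#' @param path CSV file path.
#' @param dialect `"auto"` (default), `"native"` or `"thunderstorm"`.
#' @return a [localization_table()].
#' @export
read_localizations <- function(path, dialect = c("auto", "native", "thunderstorm")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_invalid(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ts_map <- c("x [nm]" = "x_nm", "y [nm]" = "y_nm", "z [nm]" = "z_nm")
  looks_ts <- all(c("x [nm]", "y [nm]") %in% names(df))
  if (dialect == "auto") dialect <- if (looks_ts) "thunderstorm" else "native"
  if (dialect == "thunderstorm") {
    if (!looks_ts)
      stop_format("not a thunderstorm-style table: missing column 'x [nm]'")
    hit <- names(df) %in% names(ts_map)
    names(df)[hit] <- ts_map[names(df)[hit]]
  }
  for (col in c("x_nm", "y_nm", "frame")) {
    if (!col %in% names(df))
      stop_format(sprintf("localization table is missing mandatory column '%s'", col))
  }
  if (!"z_nm" %in% names(df)) {
    warning("no z column found; z_nm set to 0", call. = FALSE)
    df$z_nm <- 0
  }
  for (col in c("x_nm", "y_nm", "z_nm", "frame")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      coerced <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(coerced) & !is.na(v))
      if (length(bad))
        stop_format(sprintf("non-numeric value in column '%s' at data row %d",
                            col, bad[1]))
      df[[col]] <- coerced
    }
  }
  localization_table(df)
}

#' Write a localization table as native CSV
#'
#' Writes the canonical header `id,frame,x_nm,y_nm,z_nm,truth_ring` plus a
#' sidecar JSON (`<path>.json`) with provenance.
#'
#' @param locs a [localization_table()].
#' @param path output CSV path.
#' @param sidecar write the provenance sidecar? (default TRUE)
#' @return `path`, invisibly.
#' @export
write_localizations <- function(locs, path, sidecar = TRUE) {
  stopifnot(inherits(locs, "localization_table"))
  utils::write.csv(as.data.frame(locs), path, row.names = FALSE)
  if (sidecar)
    write_sidecar(path, list(kind = "localization_table", n = nrow(locs)))
  invisible(path)
}

#' Read / write neurite traces as CSV (`vertex,x_nm,y_nm,z_nm`)
#' @param path CSV path.
#' @return [read_trace()]: a [neurite_trace()].
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  for (col in c("x_nm", "y_nm", "z_nm"))
    if (!col %in% names(df))
      stop_format(sprintf("trace file is missing column '%s'", col))
  if ("vertex" %in% names(df)) df <- df[order(df$vertex), ]
  neurite_trace(as.matrix(df[, c("x_nm", "y_nm", "z_nm")]))
}

#' @rdname read_trace
#' @param trace a [neurite_trace()].
#' @param sidecar write the provenance sidecar?
#' @export
write_trace <- function(trace, path, sidecar = TRUE) {
  stopifnot(inherits(trace, "neurite_trace"))
  df <- data.frame(vertex = seq_len(nrow(trace$vertices)),
                   x_nm = trace$vertices[, 1],
                   y_nm = trace$vertices[, 2],
                   z_nm = trace$vertices[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  if (sidecar)
    write_sidecar(path, list(kind = "neurite_trace",
                             length_nm = trace_length(trace)))
  invisible(path)
}

#' Read / write FRAP traces as CSV (`t_s,roi,reference`)
#' @param path CSV path.
#' @param t_bleach_s bleach time (default 0; traces from [simulate_frap()]
#'   put the bleach at t = 0).
#' @return [read_frap_trace()]: a [frap_trace()].
#' @export
read_frap_trace <- function(path, t_bleach_s = 0) {
  df <- utils::read.csv(path)
  for (col in c("t_s", "roi", "reference"))
    if (!col %in% names(df))
      stop_format(sprintf("FRAP trace file is missing column '%s'", col))
  frap_trace(df, t_bleach_s = t_bleach_s)
}

#' @rdname read_frap_trace
#' @param trace a [frap_trace()].
#' @param sidecar write the provenance sidecar?
#' @export
write_frap_trace <- function(trace, path, sidecar = TRUE) {
  stopifnot(inherits(trace, "frap_trace"))
  utils::write.csv(as.data.frame(trace)[, c("t_s", "roi", "reference")],
                   path, row.names = FALSE)
  if (sidecar)
    write_sidecar(path, list(kind = "frap_trace",
                             t_bleach_s = attr(trace, "t_bleach_s")))
  invisible(path)
}

#' Write / read an image as single-channel float TIFF
#'
#' Pixel values are scaled to `[0, 1]` for storage; the scale factor,
#' pixel size and origin go to the sidecar JSON, which [read_image_tiff()]
#' uses to restore the original values.
#'
#' @param image an `mps_image`.
#' @param path TIFF path.
#' @return `path` invisibly; [read_image_tiff()] returns an `mps_image`.
#' @export
write_image_tiff <- function(image, path) {
  stopifnot(inherits(image, "mps_image"))
  px <- image$pixels
  scale <- max(px, 1e-12)
  tiff::writeTIFF(px / scale, path, bits.per.sample = 32L)
  write_sidecar(path, list(kind = "image", scale = scale,
                           pixel_size_nm = image$pixel_size_nm,
                           origin_nm = image$origin_nm))
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  scale <- 1; pxsize <- 1; origin <- c(0, 0)
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!is.null(meta$scale)) scale <- meta$scale
    if (!is.null(meta$pixel_size_nm)) pxsize <- meta$pixel_size_nm
    if (!is.null(meta$origin_nm)) origin <- meta$origin_nm
  }
  mps_image(px * scale, pixel_size_nm = pxsize, origin_nm = origin)
}

#' Render localizations as a conventional-style super-resolution image
#'
#' Depicts each localization as a unit-integral 2D Gaussian of sd
#' `sigma_nm`, integrated exactly over each pixel (separable normal CDF
#' differences) and truncated at 4 sigma, so the image integral equals the
#' number of localizations to well within 0.1%. Rendering is linear in the
#' localization set.
#'
#' @param locs a [localization_table()] (may be empty: yields a zero image).
#' @param pixel_size_nm output pixel pitch (default 20).
#' @param sigma_nm Gaussian sd per localization (> 0, default 20).
#' @param origin_nm optional c(x0, y0); default: localization minimum
#'   snapped to the pixel grid, with a 4-sigma margin.
#' @param shape_px optional c(rows, cols); default: cover all
#'   localizations plus the margin.
#' @return an `mps_image`.
#' @export
render_gaussian <- function(locs, pixel_size_nm = 20, sigma_nm = 20,
                            origin_nm = NULL, shape_px = NULL) {
  check_scalar(pixel_size_nm, "pixel_size_nm", positive = TRUE)
  check_scalar(sigma_nm, "sigma_nm", positive = TRUE)
  p <- pixel_size_nm
  margin <- 4 * sigma_nm
  if (nrow(locs) == 0L) {
    if (is.null(shape_px)) shape_px <- c(1L, 1L)
    if (is.null(origin_nm)) origin_nm <- c(0, 0)
    return(mps_image(matrix(0, shape_px[1], shape_px[2]), p, origin_nm))
  }
  x <- locs$x_nm; y <- locs$y_nm
  if (is.null(origin_nm))
    origin_nm <- floor(c(min(x) - margin, min(y) - margin) / p) * p
  if (is.null(shape_px)) {
    shape_px <- c(ceiling((max(y) + margin - origin_nm[2]) / p),
                  ceiling((max(x) + margin - origin_nm[1]) / p))
  }
  ny <- shape_px[1]; nx <- shape_px[2]
  img <- matrix(0, ny, nx)
  xedges <- origin_nm[1] + (0:nx) * p
  yedges <- origin_nm[2] + (0:ny) * p
  for (k in seq_along(x)) {
    j0 <- max(1L, floor((x[k] - margin - origin_nm[1]) / p) + 1L)
    j1 <- min(nx, floor((x[k] + margin - origin_nm[1]) / p) + 1L)
    i0 <- max(1L, floor((y[k] - margin - origin_nm[2]) / p) + 1L)
    i1 <- min(ny, floor((y[k] + margin - origin_nm[2]) / p) + 1L)
    if (j0 > j1 || i0 > i1) next
    wx <- diff(stats::pnorm(xedges[j0:(j1 + 1L)], mean = x[k], sd = sigma_nm))
    wy <- diff(stats::pnorm(yedges[i0:(i1 + 1L)], mean = y[k], sd = sigma_nm))
    img[i0:i1, j0:j1] <- img[i0:i1, j0:j1] + outer(wy, wx)
  }
  mps_image(img, p, origin_nm)
}
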