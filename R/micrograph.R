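#' Calibrated grayscale micrograph
#'
#' Container for a 2-D intensity field together with its identifier and,
#' once calibrated, its pixel size. Intensities are expected in `[0, 1]`;
#' `scale` is the pixel side in microns (microns per pixel), i.e.
#' `scale = 1 / pixels_per_micron`.
#'
#' @param pixels Numeric matrix of intensities in `[0, 1]`. Rows index the
#'   image's M dimension, columns its N dimension.
#' @param name Image identifier, normally the file name.
#' @param scale Microns per pixel, strictly positive, or `NULL` while
#'   uncalibrated.
#' @return An object of class `micrograph`.
#' @export
micrograph <- function(pixels, name = "image", scale = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must have at least one pixel in each dimension", call. = FALSE)
  if (any(!is.finite(pixels)))
    stop("image intensities must all be finite", call. = FALSE)
  if (min(pixels) < 0 || max(pixels) > 1)
    stop("image intensities must lie in [0, 1]; normalize first", call. = FALSE)
  if (!is.null(scale)) {
    if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale <= 0)
      stop("`scale` must be a single positive number (microns per pixel)",
           call. = FALSE)
  }
  structure(list(pixels = pixels, name = as.character(name), scale = scale),
            class = "micrograph")
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("<micrograph> %s: %d x %d px, scale = %s\n", x$name,
              nrow(x$pixels), ncol(x$pixels),
              if (is.null(x$scale)) "uncalibrated"
              else sprintf("%.5g um/px", x$scale)))
  invisible(x)
}

#' @export
dim.micrograph <- function(x) dim(x$pixels)

#' Read a pixels-per-micron calibration file
#'
#' The calibration is a JSON object mapping image names to the number of
#' pixels per micron, e.g. `{"sample1.tif": 20.0}`. Looking up a name that
#' is not present is an error, never a silent default: mixing up scales
#' silently would corrupt every micron-unit measurement downstream.
#'
#' @param path Path to the JSON calibration file.
#' @return Named numeric vector with class `scale_calibration`.
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop("calibration file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path)
  vals <- vapply(raw, function(v) as.numeric(v[[1L]]), numeric(1))
  scale_calibration(vals)
}

#' Construct a calibration mapping directly
#'
#' @param pixels_per_micron Named numeric vector, image name to pixels per
#'   micron; every value must be strictly positive.
#' @return Named numeric vector with class `scale_calibration`.
#' @export
scale_calibration <- function(pixels_per_micron) {
  v <- unlist(pixels_per_micron)
  if (length(v) == 0L || is.null(names(v)) || any(!nzchar(names(v))))
    stop("calibration must be a non-empty named mapping", call. = FALSE)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("every pixels-per-micron value must be strictly positive", call. = FALSE)
  structure(v, class = "scale_calibration")
}

#' Look up the micron-per-pixel scale for an image
#'
#' @param calibration A `scale_calibration`.
#' @param name Image name.
#' @return `1 / pixels_per_micron[name]` in microns per pixel.
#' @export
calibration_scale <- function(calibration, name) {
  if (!name %in% names(calibration))
    stop("no calibration entry for image '", name, "'", call. = FALSE)
  1 / unname(calibration[[name]])
}

#' Convert a raster to grayscale
#'
#' 2-D input is returned unchanged; 3-channel input is combined with the
#' ITU-R 709 luma weights (0.2125, 0.7154, 0.0721). Any other channel
#' count is a format error.
#'
#' @param raster Numeric matrix or M x N x 3 array.
#' @return Numeric matrix.
#' @export
to_grayscale <- function(raster) {
  if (is.matrix(raster)) return(raster)
  if (length(dim(raster)) == 3L && dim(raster)[3L] == 3L) {
    w <- c(0.2125, 0.7154, 0.0721)
    return(raster[, , 1L] * w[1L] + raster[, , 2L] * w[2L] + raster[, , 3L] * w[3L])
  }
  stop("raster must be 2-D or have exactly 3 channels, got dims ",
       paste(dim(raster), collapse = "x"), call. = FALSE)
}

#' Min-max normalize intensities to [0, 1]
#'
#' A zero-dynamic-range (constant) image is normalized to all zeros with a
#' warning rather than an error, so a blank field does not abort a batch.
#'
#' @param pixels Numeric matrix.
#' @return Matrix with values in `[0, 1]`.
#' @export
normalize_intensity <- function(pixels) {
  rng <- range(pixels)
  if (any(!is.finite(rng))) stop("intensities must be finite", call. = FALSE)
  if (rng[1L] == rng[2L]) {
    warning("zero dynamic range: image normalized to all zeros")
    return(array(0, dim = dim(pixels)))
  }
  (pixels - rng[1L]) / (rng[2L] - rng[1L])
}

#' Load a micrograph from a TIFF or PNG file
#'
#' Reads the raster, converts to grayscale if needed, min-max normalizes
#' to `[0, 1]`, and attaches the calibrated scale
#' `1 / pixels_per_micron[name]`. The image name used for the calibration
#' lookup is the file's base name.
#'
#' @param path Path to a TIFF or PNG image (8 or 16 bit, single channel or
#'   RGB).
#' @param calibration A `scale_calibration`; must contain the image name.
#' @return A calibrated [micrograph()].
#' @export
load_micrograph <- function(path, calibration) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  name <- basename(path)
  scale <- calibration_scale(calibration, name)
  ext <- tolower(tools::file_ext(path))
  raster <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format '.", ext, "' (expected TIFF or PNG)",
         call. = FALSE))
  gs <- to_grayscale(raster)
  micrograph(normalize_intensity(gs), name = name, scale = scale)
}

#' Write a micrograph or matrix as a 16-bit grayscale TIFF
#'
#' @param x A `micrograph` or numeric matrix with values in `[0, 1]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_micrograph <- function(x, path) {
  px <- if (inherits(x, "micrograph")) x$pixels else x
  tiff::writeTIFF(px, path, bits.per.sample = 16L)
  invisible(path)
}
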