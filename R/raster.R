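#' Raster image container
#'
#' A `raster_image` is a plain numeric matrix of non-negative integer-valued
#' intensities (arbitrary units) carrying a `bit_depth` attribute (8 or 16).
#' Matrices are indexed `[row, col]`, 1-based, row increasing downward; every
#' module of the package shares this convention.
#'
#' @param pixels numeric matrix of intensities in `[0, 2^bit_depth - 1]`.
#' @param bit_depth integer, 8 or 16.
#' @return object of class `raster_image` (a matrix with attributes).
#' @export
raster_image <- function(pixels, bit_depth = 8L) {
  if (!is.matrix(pixels) || nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("'pixels' must be a non-empty matrix")
  if (!bit_depth %in% c(8L, 16L))
    stop("'bit_depth' must be 8 or 16")
  mx <- 2^bit_depth - 1
  if (any(pixels < 0) || any(pixels > mx))
    stop("intensities must lie in [0, ", mx, "]")
  structure(round(pixels), bit_depth = as.integer(bit_depth),
            class = c("raster_image", "matrix", "array"))
}

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf("<raster_image> %d x %d, %d-bit, intensity range [%g, %g]\n",
              nrow(x), ncol(x), bit_depth(x), min(x), max(x)))
  invisible(x)
}

#' Bit depth and intensity ceiling of a raster image
#' @param image a `raster_image`.
#' @return `bit_depth()`: 8 or 16; `max_value()`: `2^bit_depth - 1`.
#' @export
bit_depth <- function(image) {
  bd <- attr(image, "bit_depth")
  if (is.null(bd)) 8L else as.integer(bd)
}

#' @rdname bit_depth
#' @export
max_value <- function(image) 2^bit_depth(image) - 1

#' Read a grayscale raster image from TIFF or PNG
#'
#' Bit depth is preserved and intensities are kept on the native integer
#' scale (0..255 or 0..65535); no rescaling is applied. Multi-plane TIFFs
#' and multi-channel images are addressed through `channel`.
#'
#' @param path file path to a `.tif`/`.tiff` or `.png` image.
#' @param channel optional 1-based plane/channel index for multi-channel
#'   files; must be omitted or 1 for single-channel images.
#' @return a [raster_image].
#' @export
load_image <- function(path, channel = NULL) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    planes <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
    if (!is.list(planes)) planes <- list(planes)
    if (is.null(channel)) channel <- 1L
    nplanes <- length(planes)
    x <- planes[[1L]]
    # a single plane with a 3rd dim is a multi-channel raster
    if (nplanes == 1L && length(dim(x)) == 3L) {
      if (channel > dim(x)[3L]) stop("channel out of range: ", channel)
      bps <- attr(x, "bits.per.sample")
      x <- x[, , channel]
    } else {
      if (channel > nplanes) stop("channel out of range: ", channel)
      x <- planes[[channel]]
      bps <- attr(x, "bits.per.sample")
      if (length(dim(x)) == 3L) x <- x[, , 1L]
    }
    bd <- if (!is.null(bps) && bps[1L] == 16) 16L else 8L
    # as.is = TRUE yields native integers already
    raster_image(matrix(as.numeric(x), nrow(x), ncol(x)), bd)
  } else if (ext == "png") {
    x <- png::readPNG(path, info = TRUE)
    info <- attr(x, "info")
    bd <- if (!is.null(info$bit.depth) && info$bit.depth == 16) 16L else 8L
    if (length(dim(x)) == 3L) {
      if (is.null(channel)) channel <- 1L
      if (channel > dim(x)[3L]) stop("channel out of range: ", channel)
      x <- x[, , channel]
    } else if (!is.null(channel) && channel != 1L) {
      stop("channel out of range: ", channel)
    }
    raster_image(matrix(round(x * (2^bd - 1)), nrow(x), ncol(x)), bd)
  } else {
    stop("unsupported image format: .", ext, " (TIFF or PNG expected)")
  }
}

#' Write a raster image to TIFF or PNG
#'
#' The inverse of [load_image()]: output is grayscale at the image's own bit
#' depth, losslessly round-trippable.
#'
#' @param image a [raster_image].
#' @param path destination path; format chosen from the extension.
#' @return `path`, invisibly.
#' @export
save_image <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  bd <- bit_depth(image)
  scaled <- unclass(image) / (2^bd - 1)
  attributes(scaled) <- list(dim = dim(image))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(scaled, path, bits.per.sample = bd)
  } else if (ext == "png") {
    png::writePNG(scaled, path)
  } else {
    stop("unsupported image format: .", ext)
  }
  invisible(path)
}

#' Threshold an image into a binary mask
#'
#' A pixel is above threshold when its intensity is strictly greater than
#' `threshold`; this makes threshold 0 on an all-zero image produce an empty
#' mask and guarantees monotone shrinkage of the mask as the threshold rises.
#'
#' @param image a [raster_image].
#' @param threshold intensity in `[0, max_value(image)]`.
#' @return binary 0/1 integer matrix of the same shape.
#' @export
apply_threshold <- function(image, threshold) {
  if (length(threshold) != 1L || is.na(threshold) ||
      threshold < 0 || threshold > max_value(image))
    stop("'threshold' must lie in [0, ", max_value(image), "]")
  m <- (unclass(image) > threshold) + 0L
  dim(m) <- dim(image)
  m
}

#' Peak signal-to-noise ratio between two images
#'
#' `10 * log10(max_value^2 / MSE)` in decibels, where MSE is the mean squared
#' pixel difference. Identical images (MSE = 0) return `Inf` — a quality-check
#' pass, not an error. Values above about 22 dB indicate an image clean
#' enough for reliable automatic boundary skeletonization.
#'
#' @param reference,test `raster_image`s of identical shape and bit depth.
#' @return PSNR in dB (possibly `Inf`).
#' @export
compute_psnr <- function(reference, test) {
  if (!identical(dim(reference), dim(test)))
    stop("images must have identical shape")
  if (bit_depth(reference) != bit_depth(test))
    stop("images must have identical bit depth")
  mse <- mean((as.numeric(reference) - as.numeric(test))^2)
  if (mse == 0) return(Inf)
  10 * log10(max_value(reference)^2 / mse)
}

#' Add zero-mean Gaussian noise to an image
#'
#' Noise is clipped (not wrapped) to `[0, max_value]`, the way a saturating
#' 8-bit display image behaves. Deterministic for a fixed seed.
#'
#' @param image a [raster_image].
#' @param sigma noise standard deviation in intensity units; `>= 0`.
#' @param seed integer RNG seed.
#' @return a noisy [raster_image] of the same shape and depth.
#' @export
add_gaussian_noise <- function(image, sigma, seed = 1L) {
  if (length(sigma) != 1L || is.na(sigma) || sigma < 0)
    stop("'sigma' must be a single non-negative number")
  if (sigma == 0) return(image)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  noisy <- as.numeric(image) + stats::rnorm(length(image), 0, sigma)
  noisy <- pmin(pmax(round(noisy), 0), max_value(image))
  dim(noisy) <- dim(image)
  raster_image(noisy, bit_depth(image))
}
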