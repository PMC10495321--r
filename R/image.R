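# RGB image container and plain-image I/O.

#' Construct an RGB image object
#'
#' The unit of exchange for all image operations: an `H x W x 3` numeric
#' array of reflectance-like values in `[0, 1]`, with optional metadata.
#'
#' @param pixels numeric `H x W x 3` array (or `H x W` matrix, replicated to
#'   three identical channels), values in `[0, 1]`.
#' @param metadata optional named list (e.g. `source`, `bit_depth`).
#' @return An object of class `rgb_image`.
#' @export
rgb_image <- function(pixels, metadata = list()) {
  if (is.matrix(pixels)) {
    pixels <- array(rep(pixels, 3L), dim = c(dim(pixels), 3L))
  }
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop("`pixels` must be an H x W x 3 array", call. = FALSE)
  }
  if (any(dim(pixels)[1:2] < 2L)) stop("image must be at least 2 x 2", call. = FALSE)
  if (!all(is.finite(pixels))) stop("image contains non-finite values", call. = FALSE)
  if (min(pixels) < 0 || max(pixels) > 1) {
    stop("pixel values must lie in [0, 1]", call. = FALSE)
  }
  structure(list(pixels = pixels, metadata = metadata), class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<rgb_image> %d x %d, range [%.3f, %.3f]\n",
              d[1], d[2], min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.rgb_image <- function(x) dim(x$pixels)

as_rgb_image <- function(x) {
  if (inherits(x, "rgb_image")) x else rgb_image(x)
}

#' Read a PNG image as an `rgb_image`
#'
#' Grayscale input is replicated to three channels; an alpha channel, if
#' present, is dropped.
#'
#' @param path path to a PNG file.
#' @return An [rgb_image()].
#' @export
read_image <- function(path) {
  px <- png::readPNG(path)
  if (is.matrix(px)) px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  rgb_image(px, metadata = list(source = path))
}

#' Write an `rgb_image` (or mask) to PNG
#'
#' Images are written as 8-bit RGB; logical masks as single-channel
#' `{0, 255}` PNG.
#'
#' @param x an [rgb_image()] or a logical matrix mask.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(x, path) {
  if (is.logical(x) && is.matrix(x)) {
    png::writePNG(x * 1, path)
  } else {
    x <- as_rgb_image(x)
    png::writePNG(pmin(pmax(x$pixels, 0), 1), path)
  }
  invisible(path)
}
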