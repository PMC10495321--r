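# Whiteboard leaf segmentation.
#
# The imaging protocol (single leaf on a white board) makes the background
# near-white, so the leaf body is recovered classically: Otsu threshold on
# the per-pixel distance from white, morphological closing, hole filling,
# and retention of the largest connected component. An externally supplied
# mask (e.g. from a trained salient-object detector) can be passed straight
# to the feature layer instead.

#' Segment the leaf body from a near-white background
#'
#' @param image an [rgb_image()] photographed/generated against a near-white
#'   background.
#' @param min_area_fraction minimum foreground area fraction; below this a
#'   "no leaf found" error is raised.
#' @return A `leaf_mask` object: `mask` (logical matrix) and
#'   `area_fraction`.
#' @export
segment_leaf <- function(image, min_area_fraction = 0.01) {
  image <- as_rgb_image(image)
  px <- image$pixels
  d <- sqrt((1 - px[, , 1])^2 + (1 - px[, , 2])^2 + (1 - px[, , 3])^2) / sqrt(3)

  thr <- EBImage::otsu(EBImage::Image(d), range = c(0, 1))
  fg <- d > thr

  fg <- EBImage::closing(fg * 1, EBImage::makeBrush(3, shape = "box"))
  fg <- EBImage::fillHull(fg)
  lab <- EBImage::imageData(EBImage::bwlabel(fg))
  nlab <- max(lab)
  if (nlab == 0) stop("no leaf found", call. = FALSE)
  sizes <- tabulate(lab[lab > 0], nbins = nlab)
  mask <- lab == which.max(sizes)

  af <- mean(mask)
  if (af < min_area_fraction || af >= 1) stop("no leaf found", call. = FALSE)
  structure(list(mask = mask, area_fraction = af), class = "leaf_mask")
}

#' Wrap a logical matrix as a leaf mask
#'
#' Use for ground-truth or externally computed masks.
#'
#' @param mask logical matrix, `TRUE` on leaf pixels.
#' @return A `leaf_mask`.
#' @export
as_leaf_mask <- function(mask) {
  if (inherits(mask, "leaf_mask")) return(mask)
  stopifnot(is.matrix(mask))
  mask <- mask > 0
  structure(list(mask = mask, area_fraction = mean(mask)), class = "leaf_mask")
}

#' @export
print.leaf_mask <- function(x, ...) {
  cat(sprintf("<leaf_mask> %d x %d, area fraction %.3f\n",
              nrow(x$mask), ncol(x$mask), x$area_fraction))
  invisible(x)
}

#' Foreground pixel table
#'
#' Returns exactly the foreground pixels of `image`, one row per pixel in
#' raster order (row-major: left to right, top to bottom), columns
#' `R`, `G`, `B`.
#'
#' @param image an [rgb_image()].
#' @param mask a `leaf_mask` or logical matrix of matching size.
#' @return An `n x 3` numeric matrix.
#' @export
masked_pixels <- function(image, mask) {
  image <- as_rgb_image(image)
  mask <- as_leaf_mask(mask)$mask
  if (!all(dim(mask) == dim(image$pixels)[1:2])) {
    stop("mask and image dimensions disagree", call. = FALSE)
  }
  if (!any(mask)) stop("mask selects no pixels", call. = FALSE)
  # raster order: transpose so rows vary fastest along image rows
  sel <- which(t(mask))
  cbind(R = t(image$pixels[, , 1])[sel],
        G = t(image$pixels[, , 2])[sel],
        B = t(image$pixels[, , 3])[sel])
}

#' Intersection-over-union of two masks
#'
#' @param a,b logical matrices or `leaf_mask` objects.
#' @return IoU in `[0, 1]`.
#' @export
mask_iou <- function(a, b) {
  a <- as_leaf_mask(a)$mask; b <- as_leaf_mask(b)$mask
  stopifnot(all(dim(a) == dim(b)))
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
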