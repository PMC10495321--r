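# Gray-level co-occurrence matrix (GLCM) texture statistics.
#
# Second-order statistics of the joint distribution of quantised gray-level
# pairs at unit offset, evaluated at the four basic azimuths (0, 45, 90,
# 135 degrees) and averaged. Energy (ASM), homogeneity (IDM), contrast
# (CON), entropy (ENT) and correlation (COR) follow the standard Haralick
# forms.

#' Quantise the masked luminance to gray levels
#'
#' Luminance (Rec. 709 weights) is linearly binned to `{0, ..., levels-1}`
#' over the foreground min-max range; background pixels are marked invalid.
#'
#' @param image an [rgb_image()].
#' @param mask a `leaf_mask` or logical matrix.
#' @param levels number of gray levels, in `[2, 256]`.
#' @return A list: `index` (integer matrix, NA outside the mask), `valid`
#'   (logical matrix), `levels`, and `degenerate` (TRUE when the foreground
#'   range collapses and all pixels map to level 0).
#' @export
quantize_gray <- function(image, mask, levels = 64L) {
  assert_scalar_number(levels, "levels", lower = 2, upper = 256)
  levels <- as.integer(levels)
  image <- as_rgb_image(image)
  mask <- as_leaf_mask(mask)$mask
  px <- image$pixels
  Y <- 0.2126 * px[, , 1] + 0.7152 * px[, , 2] + 0.0722 * px[, , 3]

  vals <- Y[mask]
  if (length(vals) == 0) stop("mask selects no pixels", call. = FALSE)
  rng <- range(vals)
  degenerate <- diff(rng) < 1e-12

  idx <- matrix(NA_integer_, nrow(Y), ncol(Y))
  if (degenerate) {
    idx[mask] <- 0L
  } else {
    q <- floor((Y[mask] - rng[1]) / (rng[2] - rng[1]) * levels)
    idx[mask] <- as.integer(pmin(q, levels - 1L))
  }
  list(index = idx, valid = mask, levels = levels, degenerate = degenerate)
}

.glcm_offsets <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L),
                      `90` = c(-1L, 0L), `135` = c(-1L, -1L))

#' Gray-level co-occurrence matrix at one azimuth
#'
#' Counts ordered gray-level pairs at the azimuth's unit offset (scaled by
#' `distance`) where both pixels are foreground-valid, symmetrises by
#' adding the transpose, and normalises to probabilities.
#'
#' @param gray output of [quantize_gray()].
#' @param distance pixel offset magnitude.
#' @param angle one of 0, 45, 90, 135 (degrees).
#' @return A `glcm_matrix`: `p` (`levels x levels` probabilities),
#'   `levels`, `distance`, `angle`.
#' @export
glcm <- function(gray, distance = 1L, angle = 0) {
  if (!as.character(angle) %in% names(.glcm_offsets)) {
    stop("`angle` must be one of 0, 45, 90, 135", call. = FALSE)
  }
  off <- .glcm_offsets[[as.character(angle)]] * as.integer(distance)
  idx <- gray$index; L <- gray$levels
  H <- nrow(idx); W <- ncol(idx)

  r1 <- seq(max(1L, 1L - off[1]), min(H, H - off[1]))
  c1 <- seq(max(1L, 1L - off[2]), min(W, W - off[2]))
  a <- idx[r1, c1, drop = FALSE]
  b <- idx[r1 + off[1], c1 + off[2], drop = FALSE]
  keep <- !is.na(a) & !is.na(b)
  if (!any(keep)) stop("no valid pixel pairs at this angle", call. = FALSE)

  code <- a[keep] * L + b[keep]
  counts <- tabulate(code + 1L, nbins = L * L)
  P <- matrix(counts, L, L, byrow = TRUE)   # row = first pixel level
  P <- P + t(P)
  P <- P / sum(P)
  structure(list(p = P, levels = L, distance = as.integer(distance),
                 angle = angle), class = "glcm_matrix")
}

#' Haralick statistics of a single-angle GLCM
#'
#' `ASM = sum p^2`; `IDM = sum p / (1 + (i-j)^2)`;
#' `CON = sum (i-j)^2 p`; `ENT = -sum p log p` (with `0 log 0 := 0`);
#' `COR = (sum i j p - u1 u2) / (s1 s2)` with `u`, `s` the marginal means
#' and SDs. `COR` is `NA` (undefined) when either marginal SD is below
#' `1e-12`.
#'
#' @param g a `glcm_matrix`.
#' @param ent_base base of the entropy logarithm (`exp(1)`, 2 or 10).
#' @return Named numeric vector `ASM`, `IDM`, `CON`, `ENT`, `COR`.
#' @export
glcm_stats <- function(g, ent_base = exp(1)) {
  stopifnot(inherits(g, "glcm_matrix"))
  P <- g$p; L <- g$levels
  i <- matrix(0:(L - 1), L, L)
  j <- t(i)

  ASM <- sum(P^2)
  IDM <- sum(P / (1 + (i - j)^2))
  CON <- sum((i - j)^2 * P)
  nz <- P > 0
  ENT <- -sum(P[nz] * log(P[nz], base = ent_base))

  pm <- rowSums(P)                 # marginals (symmetric: rows == cols)
  u1 <- sum((0:(L - 1)) * pm)
  s1 <- sqrt(sum((0:(L - 1) - u1)^2 * pm))
  qm <- colSums(P)
  u2 <- sum((0:(L - 1)) * qm)
  s2 <- sqrt(sum((0:(L - 1) - u2)^2 * qm))
  COR <- if (s1 < 1e-12 || s2 < 1e-12) NA_real_ else {
    (sum(i * j * P) - u1 * u2) / (s1 * s2)
  }
  c(ASM = ASM, IDM = IDM, CON = CON, ENT = ENT, COR = COR)
}

#' Direction-averaged GLCM texture features
#'
#' Per-angle [glcm_stats()] averaged arithmetically over the four azimuths.
#' The COR average skips undefined angles; if all four are undefined, COR
#' is `NA`.
#'
#' @param image an [rgb_image()].
#' @param mask a `leaf_mask` or logical matrix.
#' @param levels gray levels for quantisation.
#' @param distance pixel offset.
#' @param ent_base entropy log base.
#' @return Named numeric vector `ASM`, `IDM`, `CON`, `ENT`, `COR`.
#' @export
texture_features <- function(image, mask, levels = 64L, distance = 1L,
                             ent_base = exp(1)) {
  gray <- quantize_gray(image, mask, levels)
  per_angle <- vapply(c(0, 45, 90, 135), function(a) {
    glcm_stats(glcm(gray, distance = distance, angle = a), ent_base = ent_base)
  }, numeric(5))
  out <- rowMeans(per_angle[c("ASM", "IDM", "CON", "ENT"), , drop = FALSE])
  cors <- per_angle["COR", ]
  COR <- if (all(is.na(cors))) NA_real_ else mean(cors, na.rm = TRUE)
  c(out, COR = COR)
}
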