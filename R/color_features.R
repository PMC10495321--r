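# Colour features over the masked leaf region.
#
# 24 features across four colour spaces, all computed from the three
# foreground channel means: the raw RGB means with their ratio/difference
# indices, chromatic (normalised) coordinates, HSV, and CIELAB (D65).

.color_feature_names <- c(
  "R", "G", "B", "G/R", "G/B", "B/R", "G-R", "G-B", "B-R",
  "(B-G-R)/(B+G)", "(B-G-R)/(R+B)", "(B-G-R)/(G+R)",
  "r", "g", "b", "gr", "gb", "br",
  "H", "S", "V", "Lab_L", "Lab_a", "Lab_b")

.texture_feature_names <- c("ASM", "IDM", "CON", "ENT", "COR")

#' Fixed feature vocabulary
#'
#' The 24 colour feature names followed by the 5 GLCM texture feature
#' names, in the fixed column order used by [extract_features()].
#'
#' @return Character vector of length 29.
#' @export
feature_names <- function() c(.color_feature_names, .texture_feature_names)

#' Names of the colour-feature block
#' @return Character vector of length 24.
#' @export
color_feature_names <- function() .color_feature_names

#' Names of the texture-feature block
#' @return Character vector of length 5.
#' @export
texture_feature_names <- function() .texture_feature_names

# guarded ratio: denominators floored at eps in magnitude
.guard <- function(x, eps = 1e-6) sign(x + (x == 0)) * pmax(abs(x), eps)

#' Colour features of the masked leaf region
#'
#' `R`, `G`, `B` are the foreground channel means (in `[0, 1]`); every
#' derived index is computed from those three means with an `eps = 1e-6`
#' denominator guard. Chromatic coordinates are `r = R/(R+G+B)` etc. with
#' `gr = g - r`, `gb = g - b`, `br = b - r`. HSV and CIELAB come from the
#' standard sRGB and sRGB(D65) conversions of the mean colour; `H` is
#' stored as degrees/360 so all features share comparable scales.
#'
#' @param image an [rgb_image()] (typically MSRCR-corrected).
#' @param mask a `leaf_mask` or logical matrix.
#' @return Named numeric vector of length 24.
#' @export
color_features <- function(image, mask) {
  pix <- masked_pixels(image, mask)
  m <- colMeans(pix)
  R <- m[["R"]]; G <- m[["G"]]; B <- m[["B"]]

  s <- R + G + B
  r <- R / .guard(s); g <- G / .guard(s); b <- B / .guard(s)

  hsv <- grDevices::rgb2hsv(R, G, B, maxColorValue = 1)
  lab <- grDevices::convertColor(matrix(c(R, G, B), nrow = 1),
                                 from = "sRGB", to = "Lab")

  out <- c(
    R, G, B,
    G / .guard(R), G / .guard(B), B / .guard(R),
    G - R, G - B, B - R,
    (B - G - R) / .guard(B + G),
    (B - G - R) / .guard(R + B),
    (B - G - R) / .guard(G + R),
    r, g, b, g - r, g - b, b - r,
    hsv["h", 1], hsv["s", 1], hsv["v", 1],
    lab[1, 1], lab[1, 2], lab[1, 3])
  stats::setNames(out, .color_feature_names)
}
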