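# Multi-scale retinex with colour restoration (MSRCR).
#
# Centre/surround decomposition in the log domain at several Gaussian
# scales, plus a chromatic restoration factor, then a per-channel
# percentile stretch. The surround at each scale is estimated by a
# Gaussian-weighted local plane fit (normalised convolution with
# first-order moments) rather than a plain blur: the fit reproduces affine
# illumination fields exactly, including at image boundaries, so a constant
# reflectance under a linear ramp maps to a constant output.

#' MSRCR parameters
#'
#' @param scales Gaussian surround SDs in pixels, strictly increasing.
#' @param weights per-scale weights, positive; normalised to sum 1.
#' @param alpha colour-restoration strength.
#' @param beta colour-restoration gain.
#' @param clip_percentiles `(low, high)` per-channel stretch percentiles.
#' @param epsilon log-domain floor.
#' @return An `msrcr_params` list.
#' @export
msrcr_params <- function(scales = c(15, 80, 250), weights = NULL,
                         alpha = 125, beta = 46,
                         clip_percentiles = c(1, 99), epsilon = 1e-6) {
  if (any(scales <= 0) || is.unsorted(scales, strictly = TRUE)) {
    stop("`scales` must be positive and strictly increasing", call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1 / length(scales), length(scales))
  if (length(weights) != length(scales) || any(weights <= 0)) {
    stop("`weights` must be positive, one per scale", call. = FALSE)
  }
  weights <- weights / sum(weights)
  lo <- clip_percentiles[1]; hi <- clip_percentiles[2]
  if (!(lo >= 0 && lo < hi && hi <= 100)) {
    stop("`clip_percentiles` must satisfy 0 <= low < high <= 100", call. = FALSE)
  }
  assert_scalar_number(epsilon, "epsilon", lower = 0, strict_lower = TRUE)
  structure(list(scales = scales, weights = weights, alpha = alpha,
                 beta = beta, clip_percentiles = c(lo, hi), epsilon = epsilon),
            class = "msrcr_params")
}

# Surround estimate: Gaussian-weighted local fit of a + b*x + c*y over the
# image support, evaluated at each pixel. Exact for affine signals,
# including at image boundaries. All scales share one FFT plan (kernels
# truncated at half the smaller image dimension), and the image-independent
# geometric moment fields are cached per (size, scales), so one image costs
# three forward FFTs per channel plus three inverse FFTs per channel-scale.
.msrcr_cache <- new.env(parent = emptyenv())

surround_geometry <- function(H, W, scales) {
  key <- paste(H, W, paste(scales, collapse = ","), sep = "|")
  hit <- .msrcr_cache[[key]]
  if (!is.null(hit)) return(hit)

  radius <- min(ceiling(3.5 * max(scales)), floor(min(H, W) / 2))
  plan <- fft_plan(H, W, 2L * radius + 1L, 2L * radius + 1L)

  yy <- matrix(seq_len(H) - (H + 1) / 2, H, W)
  xx <- matrix(seq_len(W) - (W + 1) / 2, H, W, byrow = TRUE)
  f_one <- fft_forward(matrix(1, H, W), plan)
  f_xx <- fft_forward(xx, plan); f_yy <- fft_forward(yy, plan)
  f_x2 <- fft_forward(xx * xx, plan); f_xy <- fft_forward(xx * yy, plan)
  f_y2 <- fft_forward(yy * yy, plan)

  per_scale <- lapply(scales, function(sigma) {
    k <- gaussian_kernel(sigma, radius = radius)
    K <- matrix(0, plan$P, plan$Q)
    K[seq_len(nrow(k)), seq_len(ncol(k))] <- k
    Kf <- stats::fft(K)
    S00 <- fft_conv_apply(f_one, Kf, plan)
    Sx  <- fft_conv_apply(f_xx, Kf, plan)
    Sy  <- fft_conv_apply(f_yy, Kf, plan)
    Sxx <- fft_conv_apply(f_x2, Kf, plan)
    Sxy <- fft_conv_apply(f_xy, Kf, plan)
    Syy <- fft_conv_apply(f_y2, Kf, plan)
    # symmetric 3x3 normal-matrix inverse via cofactors, vectorised
    c11 <- Sxx * Syy - Sxy * Sxy
    c12 <- Sy * Sxy - Sx * Syy
    c13 <- Sx * Sxy - Sy * Sxx
    c22 <- S00 * Syy - Sy * Sy
    c23 <- Sx * Sy - S00 * Sxy
    c33 <- S00 * Sxx - Sx * Sx
    det <- S00 * c11 + Sx * c12 + Sy * c13
    list(Kf = Kf, S00 = S00, c11 = c11, c12 = c12, c13 = c13,
         c22 = c22, c23 = c23, c33 = c33, det = det,
         ok = abs(det) > 1e-12)
  })

  geo <- list(plan = plan, xx = xx, yy = yy, per_scale = per_scale)
  if (length(ls(.msrcr_cache)) > 6) rm(list = ls(.msrcr_cache), envir = .msrcr_cache)
  .msrcr_cache[[key]] <- geo
  geo
}

# surrounds for one channel at every scale: list of H x W matrices
plane_fit_surrounds <- function(I, geo) {
  plan <- geo$plan
  fI <- fft_forward(I, plan)
  fxI <- fft_forward(geo$xx * I, plan)
  fyI <- fft_forward(geo$yy * I, plan)
  lapply(geo$per_scale, function(s) {
    T0 <- fft_conv_apply(fI, s$Kf, plan)
    Tx <- fft_conv_apply(fxI, s$Kf, plan)
    Ty <- fft_conv_apply(fyI, s$Kf, plan)
    a <- (s$c11 * T0 + s$c12 * Tx + s$c13 * Ty) / s$det
    b <- (s$c12 * T0 + s$c22 * Tx + s$c23 * Ty) / s$det
    d <- (s$c13 * T0 + s$c23 * Tx + s$c33 * Ty) / s$det
    out <- a + b * geo$xx + d * geo$yy
    out[!s$ok] <- (T0 / pmax(s$S00, 1e-12))[!s$ok]
    out
  })
}

#' Multi-scale retinex with colour restoration
#'
#' Per channel `i`, `MSR_i = sum_k w_k * (log(I_i + eps) - log(S_ki + eps))`
#' with `S_ki` the scale-`k` surround of channel `i`, multiplied by the
#' restoration factor `C_i = beta * log(alpha * (I_i + eps) /
#' (I_R + I_G + I_B + 3 eps))`, then per-channel percentile clip and rescale
#' to `[0, 1]`. Output dimensions equal input. A degenerate (constant)
#' result maps to a 0.5 constant and is flagged in
#' `metadata$msrcr_degenerate`.
#'
#' @param image an [rgb_image()].
#' @param params an [msrcr_params()].
#' @return The corrected [rgb_image()].
#' @export
msrcr <- function(image, params = msrcr_params()) {
  image <- as_rgb_image(image)
  stopifnot(inherits(params, "msrcr_params"))
  px <- image$pixels
  eps <- params$epsilon

  geo <- surround_geometry(dim(px)[1], dim(px)[2], params$scales)
  msr <- array(0, dim = dim(px))
  for (ch in 1:3) {
    surrounds <- plane_fit_surrounds(px[, , ch], geo)
    acc <- 0
    for (k in seq_along(params$scales)) {
      acc <- acc + params$weights[k] *
        (log(px[, , ch] + eps) - log(pmax(surrounds[[k]], 0) + eps))
    }
    msr[, , ch] <- acc
  }

  chroma_sum <- px[, , 1] + px[, , 2] + px[, , 3] + 3 * eps
  out <- array(0, dim = dim(px))
  degenerate <- logical(3)
  for (ch in 1:3) {
    C <- params$beta * log(params$alpha * (px[, , ch] + eps) / chroma_sum)
    v <- C * msr[, , ch]
    q <- stats::quantile(v, params$clip_percentiles / 100, names = FALSE)
    if (diff(q) < 1e-8) {
      out[, , ch] <- 0.5
      degenerate[ch] <- TRUE
    } else {
      out[, , ch] <- pmin(pmax((v - q[1]) / (q[2] - q[1]), 0), 1)
    }
  }

  meta <- image$metadata
  if (any(degenerate)) meta$msrcr_degenerate <- which(degenerate)
  rgb_image(out, metadata = meta)
}
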