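# Internal helpers: seeded evaluation, FFT convolution, argument checks.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state, so seeded package functions never perturb user
#' simulations.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream of child seeds from one parent seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (strict_lower && x <= lower) {
    stop(sprintf("`%s` must be > %g", name, lower), call. = FALSE)
  }
  if (!strict_lower && x < lower) {
    stop(sprintf("`%s` must be >= %g", name, lower), call. = FALSE)
  }
  if (x > upper) stop(sprintf("`%s` must be <= %g", name, upper), call. = FALSE)
  invisible(x)
}

# --- FFT machinery -----------------------------------------------------------

# 2-D linear convolution of `x` (H x W) with a centred symmetric kernel,
# via zero-padded FFT. Returns the H x W "same" part. Kernel is supplied as
# a full (2r+1)^2 matrix.
conv2_fft <- function(x, kernel) {
  H <- nrow(x); W <- ncol(x)
  kh <- nrow(kernel); kw <- ncol(kernel)
  P <- stats::nextn(H + kh - 1L, c(2L, 3L))
  Q <- stats::nextn(W + kw - 1L, c(2L, 3L))
  X <- matrix(0, P, Q); X[seq_len(H), seq_len(W)] <- x
  K <- matrix(0, P, Q); K[seq_len(kh), seq_len(kw)] <- kernel
  out <- Re(stats::fft(stats::fft(X) * stats::fft(K), inverse = TRUE)) / (P * Q)
  r <- (kh - 1L) %/% 2L; c0 <- (kw - 1L) %/% 2L
  out[r + seq_len(H), c0 + seq_len(W)]
}

# Precompute padded FFT of an image block for repeated convolution with
# kernels of a common padded size.
fft_plan <- function(H, W, kh, kw) {
  P <- stats::nextn(H + kh - 1L, c(2L, 3L))
  Q <- stats::nextn(W + kw - 1L, c(2L, 3L))
  list(H = H, W = W, kh = kh, kw = kw, P = P, Q = Q)
}

fft_forward <- function(x, plan) {
  X <- matrix(0, plan$P, plan$Q)
  X[seq_len(plan$H), seq_len(plan$W)] <- x
  stats::fft(X)
}

fft_conv_apply <- function(Xf, Kf, plan) {
  out <- Re(stats::fft(Xf * Kf, inverse = TRUE)) / (plan$P * plan$Q)
  r <- (plan$kh - 1L) %/% 2L; c0 <- (plan$kw - 1L) %/% 2L
  out[r + seq_len(plan$H), c0 + seq_len(plan$W)]
}

# Centred 2-D Gaussian kernel, truncated at `radius` (default 3.5 sigma),
# normalised to sum 1.
gaussian_kernel <- function(sigma, radius = NULL, max_radius = Inf) {
  assert_scalar_number(sigma, "sigma", lower = 0, strict_lower = TRUE)
  if (is.null(radius)) radius <- ceiling(3.5 * sigma)
  radius <- as.integer(min(radius, max_radius))
  s <- seq(-radius, radius)
  g <- exp(-s^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# Gaussian blur of a matrix (zero-influence outside the support is corrected
# by mask normalisation, so constants are preserved exactly).
gaussian_blur <- function(x, sigma) {
  k <- gaussian_kernel(sigma, max_radius = max(dim(x)))
  num <- conv2_fft(x, k)
  den <- conv2_fft(matrix(1, nrow(x), ncol(x)), k)
  num / den
}

# --- misc --------------------------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a
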