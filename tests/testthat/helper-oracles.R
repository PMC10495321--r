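# Independent brute-force oracles and small fixture builders used across
# the test files. Oracles deliberately use naive loops / direct formulas,
# not the package's vectorised implementations.

# Brute-force GLCM: enumerate every ordered pixel pair at the offset,
# symmetrise, normalise.
oracle_glcm <- function(idx, valid, L, distance = 1, angle = 0) {
  off <- switch(as.character(angle),
                `0` = c(0, 1), `45` = c(-1, 1),
                `90` = c(-1, 0), `135` = c(-1, -1)) * distance
  P <- matrix(0, L, L)
  H <- nrow(idx); W <- ncol(idx)
  for (r in seq_len(H)) for (cc in seq_len(W)) {
    r2 <- r + off[1]; c2 <- cc + off[2]
    if (r2 >= 1 && r2 <= H && c2 >= 1 && c2 <= W &&
        valid[r, cc] && valid[r2, c2]) {
      P[idx[r, cc] + 1, idx[r2, c2] + 1] <- P[idx[r, cc] + 1, idx[r2, c2] + 1] + 1
    }
  }
  P <- P + t(P)
  P / sum(P)
}

# Direct-formula Haralick statistics (double loops).
oracle_glcm_stats <- function(P) {
  L <- nrow(P)
  ASM <- 0; IDM <- 0; CON <- 0; ENT <- 0; sij <- 0
  for (i in 0:(L - 1)) for (j in 0:(L - 1)) {
    p <- P[i + 1, j + 1]
    ASM <- ASM + p^2
    IDM <- IDM + p / (1 + (i - j)^2)
    CON <- CON + (i - j)^2 * p
    if (p > 0) ENT <- ENT - p * log(p)
    sij <- sij + i * j * p
  }
  pm <- rowSums(P); qm <- colSums(P)
  u1 <- sum((0:(L - 1)) * pm); u2 <- sum((0:(L - 1)) * qm)
  s1 <- sqrt(sum((0:(L - 1) - u1)^2 * pm))
  s2 <- sqrt(sum((0:(L - 1) - u2)^2 * qm))
  COR <- if (s1 < 1e-12 || s2 < 1e-12) NA_real_ else (sij - u1 * u2) / (s1 * s2)
  c(ASM = ASM, IDM = IDM, CON = CON, ENT = ENT, COR = COR)
}

# Direct covariance-formula Pearson correlation.
oracle_pearson <- function(x, y) {
  dx <- x - mean(x); dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Direct-formula regression metrics.
oracle_metrics <- function(y, yhat) {
  c(R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2),
    RMSE = sqrt(sum((yhat - y)^2) / length(y)),
    MAPE = mean(abs((yhat - y) / y)))
}

# A small uniform-colour leaf image: `col` inside a centred disk on a
# near-white board.
disk_leaf_image <- function(size = 32L, col = c(0.3, 0.6, 0.25),
                            radius = size / 4, background = 0.96) {
  yy <- matrix(seq_len(size) - (size + 1) / 2, size, size)
  xx <- t(yy)
  mask <- xx^2 + yy^2 <= radius^2
  px <- array(background, c(size, size, 3))
  for (ch in 1:3) {
    plane <- px[, , ch]; plane[mask] <- col[ch]; px[, , ch] <- plane
  }
  list(image = rgb_image(px), mask = mask)
}

# Feature table + linear target without any imaging, for model-layer tests.
toy_regression <- function(n = 40, d = 5, noise = 0.1, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * d), n, d,
              dimnames = list(NULL, paste0("x", seq_len(d))))
  beta <- seq_len(d) / d
  y <- as.numeric(X %*% beta) + rnorm(n, sd = noise) + 1.5
  list(X = X, y = y)
}
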