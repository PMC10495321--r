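test_that("pearson screening matches the covariance-formula oracle", {
  set.seed(41)
  X <- matrix(rnorm(30 * 6), 30, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- rnorm(30)
  rep <- pearson_screen(X, y, threshold = 0.2)$report
  for (j in 1:6) {
    expect_equal(rep$r[j], oracle_pearson(X[, j], y), tolerance = 1e-12)
  }
  expect_identical(rep$selected, abs(rep$r) > 0.2)
})

test_that("screening handles exact, negative and constant columns", {
  y <- c(1, 3, 2, 5, 4)
  X <- cbind(same = y, anti = -y, const = rep(2, 5))
  rep <- pearson_screen(X, y)$report
  expect_equal(rep$r[1], 1); expect_true(rep$selected[1])
  expect_equal(rep$r[2], -1); expect_true(rep$selected[2])
  expect_equal(rep$r[3], 0); expect_true(rep$constant[3]); expect_false(rep$selected[3])

  x <- c(1, 2, 3, 4); yy <- c(2, 4, 5, 9)
  r <- pearson_screen(cbind(x = x), yy, 0.7)$report$r
  expect_equal(r, oracle_pearson(x, yy), tolerance = 1e-12)
  expect_equal(r, 0.9648, tolerance = 1e-4)

  expect_error(pearson_screen(cbind(a = 1:2), 1:2), "3 samples")
  expect_error(pearson_screen(cbind(a = 1:5), rep(1, 5)), "constant")
})

test_that("PCA reproduces the rank-1 and white-data limits", {
  set.seed(2)
  z <- rnorm(50)
  X <- cbind(a = z, b = 2 * z + 3)         # perfectly correlated pair
  m <- fit_pca(X, block = "CF")
  expect_equal(m$eigenvalues, c(2, 0), tolerance = 1e-9)
  expect_equal(m$cvcr, c(100, 100), tolerance = 1e-9)

  Xw <- matrix(rnorm(4000 * 4), ncol = 4, dimnames = list(NULL, letters[1:4]))
  mw <- fit_pca(Xw)
  expect_equal(mw$eigenvalues, rep(1, 4), tolerance = 0.1)
})

test_that("PCA bookkeeping identities hold on random data", {
  set.seed(3)
  X <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(NULL, paste0("v", 1:6)))
  X[, 2] <- X[, 1] * 0.8 + rnorm(40, sd = 0.3)
  m <- fit_pca(X)
  expect_equal(sum(m$eigenvalues), 6, tolerance = 1e-6)
  expect_true(all(diff(m$eigenvalues) <= 1e-12))
  expect_equal(m$cvcr[length(m$cvcr)], 100, tolerance = 1e-6)
  # CVCR increments proportional to eigenvalues
  expect_equal(diff(c(0, m$cvcr)), m$eigenvalues / sum(m$eigenvalues) * 100,
               tolerance = 1e-9)
  # deterministic sign convention
  for (k in seq_len(ncol(m$loadings))) {
    expect_gte(m$loadings[which.max(abs(m$loadings[, k])), k], 0)
  }

  # training scores: zero mean, variances equal to eigenvalues
  S <- pca_transform(m, X, k = 6)
  expect_lt(max(abs(colMeans(S))), 1e-9)
  expect_equal(apply(S, 2, function(s) sum(s^2) / (nrow(X) - 1)),
               stats::setNames(m$eigenvalues, colnames(S)), tolerance = 1e-6)
})

test_that("PCA guards degenerate blocks", {
  expect_error(fit_pca(cbind(a = rep(1, 10), b = rep(2, 10))), "constant")
  expect_warning(fit_pca(cbind(a = rnorm(10), b = rep(1, 10))), "constant column")
  expect_warning(fit_pca(matrix(rnorm(12), 3, 4,
                                dimnames = list(NULL, paste0("c", 1:4)))),
                 "rank deficient")
})

test_that("Kaiser retention reproduces the variance-table worked examples", {
  expect_equal(kaiser_retain(c(14.427, 5.465, 2.249, 0.483, 0.314)), 3L)
  expect_equal(kaiser_retain(c(3.319, 0.546, 0.244, 0.041, 0.002)), 1L)
  expect_warning(k <- kaiser_retain(c(0.9, 0.8)), "retaining one")
  expect_equal(k, 1L)
  expect_error(kaiser_retain(numeric(0)), "empty")
})

test_that("pca_transform requires the training columns and handles one row", {
  set.seed(4)
  X <- matrix(rnorm(30 * 3), 30, 3, dimnames = list(NULL, c("a", "b", "c")))
  m <- fit_pca(X)
  expect_error(pca_transform(m, X[, 1:2]), "missing feature")
  one <- pca_transform(m, X[1, , drop = FALSE])
  expect_equal(nrow(one), 1)
  expect_true(all(is.finite(one)))
})

test_that("variants assemble the documented designs with provenance", {
  set.seed(10)
  n <- 40
  nv <- runif(n, 0.8, 2.2)
  tab <- as.data.frame(matrix(rnorm(n * 29, sd = 0.05), n, 29))
  names(tab) <- feature_names()
  tab$G <- 0.8 - 0.1 * nv + rnorm(n, sd = 0.01)
  tab$R <- 0.6 - 0.15 * nv + rnorm(n, sd = 0.01)
  tab$ASM <- 0.2 + 0.1 * nv + rnorm(n, sd = 0.01)

  sel <- fit_selectors(tab, nv, threshold = 0.7)
  cf <- assemble_variant("CF-SCT", tab, sel)
  expect_true(all(c("CF:G", "CF:R") %in% cf$provenance))
  expect_equal(ncol(cf$X), length(cf$provenance))

  ct <- assemble_variant("C-T-PCA", tab, sel)
  expect_equal(ncol(ct$X), sel$pca_cf$k_retained + sel$pca_tf$k_retained)
  expect_true(all(grepl("^(CF|TF)PC", colnames(ct$X))))

  ctif <- assemble_variant("CTIF-SCT", tab, sel)
  expect_equal(ncol(ctif$X),
               ncol(assemble_variant("CF-SCT", tab, sel)$X) +
               ncol(assemble_variant("TF-SCT", tab, sel)$X))

  # pure-noise target: nothing survives |r| > 0.999
  sel_none <- fit_selectors(tab, rnorm(n), threshold = 0.999)
  expect_error(assemble_variant("CF-SCT", tab, sel_none), "CF-SCT")
})

test_that("per-fold selector fitting differs from full-data fitting", {
  set.seed(11)
  n <- 30
  tab <- as.data.frame(matrix(rnorm(n * 29), n, 29))
  names(tab) <- feature_names()
  y <- rnorm(n) + 0.5 * tab$G
  full <- fit_selectors(tab, y, threshold = 0.2)
  fold <- suppressWarnings(fit_selectors(tab[1:20, ], y[1:20], threshold = 0.2))
  expect_false(isTRUE(all.equal(full$pca_cf$center, fold$pca_cf$center)))
  s_full <- pca_transform(full$pca_cf, tab[21:30, ])
  s_fold <- pca_transform(fold$pca_cf, tab[21:30, ],
                          k = ncol(s_full))
  expect_gt(max(abs(s_full - s_fold)), 1e-6)
})
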