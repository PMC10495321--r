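test_that("k-fold partitions are disjoint, covering, balanced and seeded", {
  f <- kfold_split(10, 5, seed = 1)
  expect_length(f, 5)
  expect_true(all(lengths(f) == 2))
  expect_setequal(unlist(f), 1:10)

  f60 <- kfold_split(60, 5, seed = 7)
  expect_true(all(lengths(f60) == 12))
  expect_setequal(unlist(f60), 1:60)

  expect_identical(kfold_split(23, 5, seed = 3), kfold_split(23, 5, seed = 3))
  expect_false(identical(kfold_split(23, 5, seed = 3), kfold_split(23, 5, seed = 4)))
  expect_error(kfold_split(4, 5), "n >= k")

  f7 <- kfold_split(7, 3, seed = 2)
  expect_lte(diff(range(lengths(f7))), 1)
})

test_that("metrics reproduce the identities and the worked triple", {
  y <- c(0.9, 1.4, 2.1, 1.7)
  expect_equal(unname(regression_metrics(y, y)), c(1, 0, 0))
  expect_equal(regression_metrics(y, rep(mean(y), 4))[["R2"]], 0)

  m <- regression_metrics(c(1, 2, 3), c(1, 2, 4))
  expect_equal(unname(m), c(0.5, sqrt(1 / 3), 1 / 9), tolerance = 1e-10)
  expect_equal(m[["RMSE"]], 0.57735, tolerance = 1e-5)
  expect_equal(m[["MAPE"]], 0.11111, tolerance = 1e-4)

  set.seed(6)
  for (i in 1:20) {
    yy <- rnorm(10, mean = 3); hh <- yy + rnorm(10, sd = 0.5)
    expect_equal(regression_metrics(yy, hh), oracle_metrics(yy, hh),
                 tolerance = 1e-12)
  }

  expect_true(is.na(regression_metrics(rep(1, 3), c(1, 1, 2))[["R2"]]))
  expect_true(is.na(regression_metrics(c(0, 1, 2), c(1, 1, 2))[["MAPE"]]))
})

test_that("the range scaler maps training data onto [-1, 1] and back", {
  toy <- toy_regression(n = 25)
  sc <- fit_scaler(toy$X, toy$y)
  Xs <- leafnitro:::scale_x(sc, toy$X)
  expect_equal(unname(apply(Xs, 2, range)), matrix(rep(c(-1, 1), 5), 2, 5))
  ys <- leafnitro:::scale_y(sc, toy$y)
  expect_equal(range(ys), c(-1, 1))
  expect_equal(leafnitro:::unscale_y(sc, ys), toy$y, tolerance = 1e-12)
})

test_that("MLR recovers exact linear coefficients and handles singularity", {
  toy <- toy_regression(n = 30, d = 4, noise = 0)
  fit <- train_model(model_spec("MLR"), toy$X, toy$y)
  expect_equal(predict(fit, toy$X), toy$y, tolerance = 1e-8)

  Xc <- cbind(toy$X, dup = toy$X[, 1])          # exactly collinear
  expect_warning(fitc <- train_model(model_spec("MLR"), Xc, toy$y), "singular")
  expect_equal(predict(fitc, Xc), toy$y, tolerance = 1e-8)
})

test_that("PLS saturates to least squares at full rank", {
  toy <- toy_regression(n = 40, d = 5, noise = 0.2)
  mlr <- train_model(model_spec("MLR"), toy$X, toy$y)
  pls <- train_model(model_spec("PLS", list(ncomp = 5)), toy$X, toy$y)
  expect_equal(predict(pls, toy$X), predict(mlr, toy$X), tolerance = 1e-6)
})

test_that("PLS agrees with the mixOmics reference on held-out predictions", {
  skip_if_not_installed("mixOmics")
  toy <- toy_regression(n = 40, d = 5, noise = 0.3)
  tr <- 1:30; te <- 31:40
  fit <- leafnitro:::pls_fit(toy$X[tr, ], toy$y[tr], ncomp = 3)
  mine <- predict(fit, toy$X[te, ])
  ref_fit <- mixOmics::pls(data.frame(toy$X[tr, ]), toy$y[tr], ncomp = 3,
                           mode = "regression", scale = TRUE)
  ref <- as.numeric(predict(ref_fit, data.frame(toy$X[te, ]))$predict[, , 3])
  expect_equal(mine, ref, tolerance = 1e-6)
})

test_that("the MLP backpropagation gradient matches finite differences", {
  set.seed(14)
  X <- matrix(rnorm(12 * 3), 12, 3); y <- rnorm(12)
  for (actname in c("identity", "logistic", "tanh", "relu")) {
    act <- leafnitro:::.mlp_act(actname)
    shapes <- leafnitro:::.mlp_shapes(3L, c(4L, 3L))
    npar <- sum(vapply(shapes, function(s) s[1] * s[2] + s[2], numeric(1)))
    par <- rnorm(npar, sd = 0.5)
    lg <- leafnitro:::.mlp_loss_grad(par, X, y, shapes, act, alpha = 1e-4)
    num <- vapply(seq_len(npar), function(i) {
      h <- 1e-6; e <- numeric(npar); e[i] <- h
      (leafnitro:::.mlp_loss_grad(par + e, X, y, shapes, act, 1e-4, FALSE)$loss -
       leafnitro:::.mlp_loss_grad(par - e, X, y, shapes, act, 1e-4, FALSE)$loss) / (2 * h)
    }, numeric(1))
    expect_equal(lg$grad, num, tolerance = 1e-4)
  }
})

test_that("BPNN fits a linear map almost exactly with identity/lbfgs", {
  toy <- toy_regression(n = 40, d = 3, noise = 0)
  fit <- train_model(model_spec("BPNN", list(hidden = 5L, activation = "identity",
                                             solver = "lbfgs")), toy$X, toy$y)
  expect_gt(regression_metrics(toy$y, predict(fit, toy$X))[["R2"]], 0.999)
})

test_that("all BPNN solvers reduce the training loss and honour the seed", {
  toy <- toy_regression(n = 30, d = 3, noise = 0.1)
  sc <- fit_scaler(toy$X, toy$y)
  Xs <- leafnitro:::scale_x(sc, toy$X); ys <- leafnitro:::scale_y(sc, toy$y)
  base <- regression_metrics(ys, rep(mean(ys), length(ys)))[["RMSE"]]
  for (solver in c("lbfgs", "adam", "sgd")) {
    f1 <- mlp_fit(Xs, ys, hidden = 8L, activation = "tanh", solver = solver,
                  max_iter = 3000L, seed = 3)
    f2 <- mlp_fit(Xs, ys, hidden = 8L, activation = "tanh", solver = solver,
                  max_iter = 3000L, seed = 3)
    expect_identical(f1$par, f2$par)
    rmse <- regression_metrics(ys, predict(f1, Xs))[["RMSE"]]
    expect_lt(rmse, base)
  }
})

test_that("stochastic families are reproducible under a fixed seed", {
  toy <- toy_regression(n = 30)
  a <- train_model(model_spec("RF", list(ntree = 50), seed = 9), toy$X, toy$y)
  b <- train_model(model_spec("RF", list(ntree = 50), seed = 9), toy$X, toy$y)
  expect_identical(predict(a, toy$X), predict(b, toy$X))

  s1 <- train_model(model_spec("SVR", list(kernel = "radial", gamma = "scale")),
                    toy$X, toy$y)
  s2 <- train_model(model_spec("SVR", list(kernel = "radial", gamma = "scale")),
                    toy$X, toy$y)
  expect_identical(predict(s1, toy$X), predict(s2, toy$X))
})

test_that("grid search traverses cells and picks the planted optimum", {
  toy <- toy_regression(n = 30, d = 3, noise = 0.05)

  single <- grid_search("PLS", toy$X, toy$y, grid = list(list(ncomp = 2)),
                        k = 3, seed = 1)
  expect_equal(single$best_params$ncomp, 2)

  # a correct-by-design cell (identity net) vs a deliberately bad one
  grid <- list(list(hidden = 2L, activation = "relu", solver = "sgd",
                    max_iter = 2L),
               list(hidden = 5L, activation = "identity", solver = "lbfgs"))
  gs <- grid_search("BPNN", toy$X, toy$y, grid = grid, k = 3, seed = 1)
  expect_equal(gs$best_index, 2)
  gs2 <- grid_search("BPNN", toy$X, toy$y, grid = grid, k = 3, seed = 1)
  expect_identical(gs$best_index, gs2$best_index)
  expect_equal(gs$cv, gs2$cv)

  expect_error(grid_search("PLS", toy$X, toy$y, grid = list()), "empty grid")
})

test_that("enlarging a grid never lowers the selected mean R-squared", {
  toy <- toy_regression(n = 35, d = 4, noise = 0.3, seed = 8)
  small <- lapply(1:2, function(k) list(ncomp = k))
  big <- lapply(1:4, function(k) list(ncomp = k))
  r_small <- grid_search("PLS", toy$X, toy$y, grid = small, k = 5, seed = 2)
  r_big <- grid_search("PLS", toy$X, toy$y, grid = big, k = 5, seed = 2)
  best <- function(r) max(r$cv$R2)
  expect_gte(best(r_big), best(r_small))
})
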