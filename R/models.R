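# Regression families: multiple linear regression (MLR), partial least
# squares (PLS1, NIPALS), support vector regression (SVR, via e1071),
# back-propagation neural network (BPNN, in-package MLP) and random forest
# (RF, via randomForest). Each family is wrapped in a common train/predict
# surface that owns the min-max [-1, 1] scaling and seeding.

#' Model specification
#'
#' @param family one of `"MLR"`, `"PLS"`, `"SVR"`, `"BPNN"`, `"RF"`.
#' @param params named list of family hyperparameters (one grid cell).
#' @param seed integer seed for stochastic families.
#' @return A `model_spec`.
#' @export
model_spec <- function(family = c("MLR", "PLS", "SVR", "BPNN", "RF", "KNN1"),
                       params = list(), seed = 1L) {
  family <- match.arg(family)
  structure(list(family = family, params = params, seed = as.integer(seed)),
            class = "model_spec")
}

# families whose inputs/targets are range-scaled to [-1, 1]
.scaled_families <- c("PLS", "SVR", "BPNN")

#' Default hyperparameter grid per family
#'
#' Grids follow the study's stated search ranges, reduced to desk-scale
#' defaults where the literal range is large (see `full` and
#' [bpnn_grid()]):
#' * MLR: no hyperparameters.
#' * PLS: `ncomp` 1..10 (clamped to the data rank at fit time).
#' * SVR: `C = 1`; kernel linear/poly/rbf/sigmoid; gamma scale/auto.
#' * BPNN: see [bpnn_grid()].
#' * RF: `ntree` in 10..100 (default a 4-point subset), terminal-node size
#'   `nodesize` 1..5.
#'
#' @param family model family.
#' @param full logical: use the full stated ranges instead of the reduced
#'   defaults (BPNN lattice, RF ntree 10..100 step 1).
#' @return List of parameter lists (grid cells).
#' @export
default_grid <- function(family, full = FALSE) {
  switch(family,
    MLR = list(list()),
    KNN1 = list(list()),
    PLS = lapply(1:10, function(k) list(ncomp = k)),
    SVR = {
      cells <- expand.grid(kernel = c("linear", "polynomial", "radial", "sigmoid"),
                           gamma = c("scale", "auto"), stringsAsFactors = FALSE)
      lapply(seq_len(nrow(cells)), function(i) {
        list(kernel = cells$kernel[i], gamma = cells$gamma[i], cost = 1)
      })
    },
    BPNN = bpnn_grid(if (full) "lattice" else "small"),
    RF = {
      ntree <- if (full) 10:100 else c(10L, 25L, 50L, 100L)
      cells <- expand.grid(ntree = ntree, nodesize = 1:5)
      lapply(seq_len(nrow(cells)), function(i) {
        list(ntree = cells$ntree[i], nodesize = cells$nodesize[i])
      })
    },
    stop(sprintf("unknown family '%s'", family), call. = FALSE))
}

#' BPNN hyperparameter grids
#'
#' `"small"` (the package default): one hidden layer of 10 or 50 neurons,
#' identity/tanh/relu activations, lbfgs. `"lattice"`: layers 1-3 x
#' neurons {10, 25, 50, 100} x all four activations x all three solvers
#' (144 cells), a denser sweep of the study's stated 1-30 x 1-100 range.
#'
#' @param kind `"small"` or `"lattice"`.
#' @return List of parameter lists.
#' @export
bpnn_grid <- function(kind = c("small", "lattice")) {
  kind <- match.arg(kind)
  if (kind == "small") {
    cells <- expand.grid(size = c(10L, 50L),
                         activation = c("identity", "tanh", "relu"),
                         solver = "lbfgs", layers = 1L,
                         stringsAsFactors = FALSE)
  } else {
    cells <- expand.grid(size = c(10L, 25L, 50L, 100L),
                         activation = c("identity", "logistic", "tanh", "relu"),
                         solver = c("lbfgs", "adam", "sgd"), layers = 1:3,
                         stringsAsFactors = FALSE)
  }
  lapply(seq_len(nrow(cells)), function(i) {
    list(hidden = rep(cells$size[i], cells$layers[i]),
         activation = cells$activation[i], solver = cells$solver[i])
  })
}

# --- PLS1 via NIPALS ---------------------------------------------------------

pls_fit <- function(X, y, ncomp) {
  X <- as.matrix(X); y <- as.numeric(y)
  xm <- colMeans(X); xs <- apply(X, 2, stats::sd); xs[xs < 1e-12] <- 1
  ym <- mean(y)
  E <- scale(X, center = xm, scale = xs); f <- y - ym
  ncomp <- max(1L, min(ncomp, ncol(X), nrow(X) - 1L))
  W <- P <- matrix(0, ncol(X), ncomp); q <- numeric(ncomp)
  for (h in seq_len(ncomp)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { ncomp <- h - 1L; break }
    w <- w / nw
    t_ <- E %*% w
    tt <- sum(t_^2)
    p <- crossprod(E, t_) / tt
    qh <- sum(f * t_) / tt
    E <- E - t_ %*% t(p)
    f <- f - t_ * qh
    W[, h] <- w; P[, h] <- p; q[h] <- qh
  }
  if (ncomp == 0L) {
    B <- matrix(0, ncol(X), 1)
  } else {
    W <- W[, seq_len(ncomp), drop = FALSE]
    P <- P[, seq_len(ncomp), drop = FALSE]
    q <- q[seq_len(ncomp)]
    B <- W %*% solve(t(P) %*% W, q)
  }
  structure(list(coef = as.numeric(B), x_center = xm, x_scale = xs,
                 y_center = ym, ncomp = ncomp), class = "pls1_model")
}

#' @export
#' @keywords internal
#' @noRd
predict.pls1_model <- function(object, newdata, ...) {
  Z <- scale(as.matrix(newdata), center = object$x_center, scale = object$x_scale)
  as.numeric(Z %*% object$coef) + object$y_center
}

# --- MLR via SVD pseudoinverse ----------------------------------------------

mlr_fit <- function(X, y) {
  X1 <- cbind(1, as.matrix(X))
  sv <- svd(X1)
  tol <- max(dim(X1)) * .Machine$double.eps * sv$d[1]
  pos <- sv$d > tol
  if (sum(pos) < ncol(X1)) {
    warning("singular design matrix; using minimum-norm least-squares solution",
            call. = FALSE)
  }
  coef <- sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
  structure(list(coef = as.numeric(coef)), class = "mlr_model")
}

#' @export
#' @keywords internal
#' @noRd
predict.mlr_model <- function(object, newdata, ...) {
  as.numeric(cbind(1, as.matrix(newdata)) %*% object$coef)
}

#' @export
#' @keywords internal
#' @noRd
predict.knn1_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  apply(X, 1, function(row) {
    d2 <- rowSums(sweep(object$X, 2, row)^2)
    object$y[which.min(d2)]
  })
}

# --- common train/predict surface -------------------------------------------

svr_gamma <- function(gamma, X) {
  if (is.numeric(gamma)) return(gamma)
  d <- ncol(X)
  switch(gamma,
    scale = { v <- stats::var(as.numeric(X)); 1 / (d * max(v, 1e-12)) },
    auto = 1 / d,
    stop(sprintf("unknown gamma '%s'", gamma), call. = FALSE))
}

#' Train a base model
#'
#' Fits one grid cell of a family on `(X, y)`. For PLS/SVR/BPNN the inputs
#' and target are range-scaled to `[-1, 1]` with a scaler fitted on this
#' training data; predictions are returned in the original target units.
#'
#' @param spec a [model_spec()].
#' @param X design matrix.
#' @param y target vector.
#' @param sample_indices optional indices of the rows of the enclosing
#'   dataset (recorded in the fold-hygiene audit log).
#' @return A `leafnitro_model`.
#' @export
train_model <- function(spec, X, y, sample_indices = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  X <- as.matrix(X)
  audit_record(paste0("fit:", spec$family), sample_indices)
  p <- spec$params

  scaler <- NULL
  Xs <- X; ys <- y
  if (spec$family %in% .scaled_families) {
    scaler <- fit_scaler(X, y)
    Xs <- scale_x(scaler, X)
    ys <- scale_y(scaler, y)
  }

  fit <- switch(spec$family,
    MLR = mlr_fit(Xs, ys),
    # 1-nearest-neighbour memoriser: resubstitution-perfect by construction,
    # used to audit out-of-fold hygiene
    KNN1 = structure(list(X = Xs, y = ys), class = "knn1_model"),
    PLS = pls_fit(Xs, ys, ncomp = p$ncomp %||% 2L),
    SVR = e1071::svm(x = Xs, y = ys, type = "eps-regression", scale = FALSE,
                     cost = p$cost %||% 1,
                     kernel = p$kernel %||% "radial",
                     gamma = svr_gamma(p$gamma %||% "scale", Xs)),
    BPNN = mlp_fit(Xs, ys, hidden = p$hidden %||% c(10L),
                   activation = p$activation %||% "identity",
                   solver = p$solver %||% "lbfgs",
                   alpha = p$alpha %||% 1e-4,
                   max_iter = p$max_iter %||% 15000L,
                   seed = spec$seed),
    RF = with_seed(spec$seed,
      randomForest::randomForest(x = Xs, y = ys,
                                 ntree = p$ntree %||% 100L,
                                 nodesize = p$nodesize %||% 5L)))

  structure(list(spec = spec, fit = fit, scaler = scaler,
                 d = ncol(X)), class = "leafnitro_model")
}

#' Predict from a trained base model
#'
#' @param object a `leafnitro_model` from [train_model()].
#' @param newdata design matrix with the training columns.
#' @param ... unused.
#' @return Predictions in the original target units.
#' @export
predict.leafnitro_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  Xs <- if (is.null(object$scaler)) X else scale_x(object$scaler, X)
  pred <- switch(object$spec$family,
    SVR = as.numeric(stats::predict(object$fit, Xs)),
    RF = as.numeric(stats::predict(object$fit, Xs)),
    as.numeric(stats::predict(object$fit, Xs)))
  if (!is.null(object$scaler)) pred <- unscale_y(object$scaler, pred)
  pred
}
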