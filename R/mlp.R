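# Back-propagation neural network (multilayer perceptron) for regression.
#
# A small, fully configurable MLP: arbitrary hidden-layer sizes, four
# activations (identity, logistic, tanh, relu), three solvers (lbfgs via
# optim, full-batch adam, momentum sgd), squared loss with L2 penalty.
# Deterministic given the seed.

.mlp_act <- function(name) {
  switch(name,
    identity = list(f = function(x) x,            df = function(x, a) 1),
    logistic = list(f = function(x) 1 / (1 + exp(-x)), df = function(x, a) a * (1 - a)),
    tanh     = list(f = tanh,                     df = function(x, a) 1 - a^2),
    relu     = list(f = function(x) pmax(x, 0),   df = function(x, a) (x > 0) * 1),
    stop(sprintf("unknown activation '%s'", name), call. = FALSE))
}

.mlp_shapes <- function(d_in, hidden) {
  sizes <- c(d_in, hidden, 1L)
  lapply(seq_len(length(sizes) - 1L), function(l) c(sizes[l], sizes[l + 1L]))
}

.mlp_unpack <- function(par, shapes) {
  W <- vector("list", length(shapes)); b <- vector("list", length(shapes))
  pos <- 0L
  for (l in seq_along(shapes)) {
    nw <- shapes[[l]][1] * shapes[[l]][2]
    W[[l]] <- matrix(par[pos + seq_len(nw)], shapes[[l]][1], shapes[[l]][2])
    pos <- pos + nw
    b[[l]] <- par[pos + seq_len(shapes[[l]][2])]
    pos <- pos + shapes[[l]][2]
  }
  list(W = W, b = b)
}

.mlp_loss_grad <- function(par, X, y, shapes, act, alpha, want_grad = TRUE) {
  n <- nrow(X)
  L <- length(shapes)
  wb <- .mlp_unpack(par, shapes)
  A <- vector("list", L + 1L); Z <- vector("list", L)
  A[[1]] <- X
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(A[[l]] %*% wb$W[[l]], 2, wb$b[[l]], "+")
    A[[l + 1]] <- if (l < L) act$f(Z[[l]]) else Z[[l]]    # linear output
  }
  r <- A[[L + 1]][, 1] - y
  pen <- sum(vapply(wb$W, function(w) sum(w^2), numeric(1)))
  loss <- 0.5 * mean(r^2) + 0.5 * alpha * pen / n
  if (!want_grad) return(list(loss = loss))

  grad <- numeric(length(par))
  delta <- matrix(r / n, ncol = 1)
  pos <- length(par)
  for (l in rev(seq_len(L))) {
    gW <- crossprod(A[[l]], delta) + alpha * wb$W[[l]] / n
    gb <- colSums(delta)
    nb <- length(gb); nw <- length(gW)
    grad[pos - nb + seq_len(nb)] <- gb; pos <- pos - nb
    grad[pos - nw + seq_len(nw)] <- as.numeric(gW); pos <- pos - nw
    if (l > 1) delta <- (delta %*% t(wb$W[[l]])) * act$df(Z[[l - 1]], A[[l]])
  }
  list(loss = loss, grad = grad)
}

#' Fit a back-propagation neural network regressor
#'
#' @param X numeric design matrix (scale inputs to `[-1, 1]` first; the
#'   model-spec layer does this automatically).
#' @param y numeric target (likewise scaled by the caller).
#' @param hidden integer vector of hidden-layer sizes.
#' @param activation one of `"identity"`, `"logistic"`, `"tanh"`, `"relu"`.
#' @param solver `"lbfgs"`, `"adam"` or `"sgd"`.
#' @param alpha L2 regularisation strength.
#' @param max_iter maximum training epochs.
#' @param learning_rate step size for adam/sgd.
#' @param tol convergence tolerance (loss improvement) for adam/sgd.
#' @param seed integer seed for the weight initialisation.
#' @return An `mlp_model` with a [predict][predict.mlp_model] method.
#' @export
mlp_fit <- function(X, y, hidden = c(10L), activation = "identity",
                    solver = c("lbfgs", "adam", "sgd"), alpha = 1e-4,
                    max_iter = 15000L, learning_rate = 1e-3, tol = 1e-8,
                    seed = 1L) {
  solver <- match.arg(solver)
  X <- as.matrix(X); y <- as.numeric(y)
  act <- .mlp_act(activation)
  shapes <- .mlp_shapes(ncol(X), as.integer(hidden))

  par0 <- with_seed(seed, {
    unlist(lapply(shapes, function(s) {
      lim <- sqrt(6 / (s[1] + s[2]))
      c(stats::runif(s[1] * s[2], -lim, lim), rep(0, s[2]))
    }))
  })

  par <- switch(solver,
    lbfgs = {
      fn <- function(p) .mlp_loss_grad(p, X, y, shapes, act, alpha, FALSE)$loss
      gr <- function(p) .mlp_loss_grad(p, X, y, shapes, act, alpha)$grad
      stats::optim(par0, fn, gr, method = "L-BFGS-B",
                   control = list(maxit = min(max_iter, 2000L)))$par
    },
    adam = {
      p <- par0; m <- v <- numeric(length(p))
      b1 <- 0.9; b2 <- 0.999; epsl <- 1e-8
      best <- Inf; stall <- 0L
      for (t in seq_len(max_iter)) {
        lg <- .mlp_loss_grad(p, X, y, shapes, act, alpha)
        m <- b1 * m + (1 - b1) * lg$grad
        v <- b2 * v + (1 - b2) * lg$grad^2
        p <- p - learning_rate * (m / (1 - b1^t)) / (sqrt(v / (1 - b2^t)) + epsl)
        if (lg$loss < best - tol) { best <- lg$loss; stall <- 0L } else stall <- stall + 1L
        if (stall >= 20L) break
      }
      p
    },
    sgd = {
      p <- par0; vel <- numeric(length(p))
      best <- Inf; stall <- 0L
      for (t in seq_len(max_iter)) {
        lg <- .mlp_loss_grad(p, X, y, shapes, act, alpha)
        vel <- 0.9 * vel - learning_rate * lg$grad
        p <- p + vel
        if (lg$loss < best - tol) { best <- lg$loss; stall <- 0L } else stall <- stall + 1L
        if (stall >= 20L) break
      }
      p
    })

  structure(list(par = par, shapes = shapes, activation = activation,
                 hidden = hidden, solver = solver, alpha = alpha),
            class = "mlp_model")
}

#' Predict from an `mlp_model`
#' @param object an `mlp_model`.
#' @param newdata design matrix on the training scale.
#' @param ... unused.
#' @return Numeric predictions.
#' @export
predict.mlp_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  act <- .mlp_act(object$activation)
  wb <- .mlp_unpack(object$par, object$shapes)
  A <- X
  L <- length(object$shapes)
  for (l in seq_len(L)) {
    Z <- sweep(A %*% wb$W[[l]], 2, wb$b[[l]], "+")
    A <- if (l < L) act$f(Z) else Z
  }
  A[, 1]
}
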