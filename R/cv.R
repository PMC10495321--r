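# Cross-validation plumbing: fold splits, evaluation metrics, the
# [-1, 1] range scaler, and a fold-hygiene audit log.

#' Seeded k-fold partition
#'
#' Disjoint index sets covering `1..n`, sizes differing by at most one,
#' from a seeded shuffle.
#'
#' @param n number of samples (`n >= k`).
#' @param k number of folds.
#' @param seed integer seed.
#' @return List of `k` integer vectors.
#' @export
kfold_split <- function(n, k = 5L, seed = 1L) {
  if (n < k) stop("need n >= k", call. = FALSE)
  perm <- with_seed(seed, sample.int(n))
  split(perm, rep_len(seq_len(k), n))
}

#' Regression evaluation metrics
#'
#' `R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`;
#' `RMSE = sqrt(mean((yhat - y)^2))`;
#' `MAPE = mean(abs((yhat - y) / y))`, reported as a fraction.
#' `R2` is `NA` for constant `y`; `MAPE` is `NA` when any `y == 0`.
#'
#' @param y observed values (length >= 2).
#' @param yhat predictions, same length.
#' @return Named numeric vector `R2`, `RMSE`, `MAPE`.
#' @export
regression_metrics <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2)
  sst <- sum((y - mean(y))^2)
  sse <- sum((y - yhat)^2)
  R2 <- if (sst < 1e-24) NA_real_ else 1 - sse / sst
  RMSE <- sqrt(mean((yhat - y)^2))
  MAPE <- if (any(y == 0)) NA_real_ else mean(abs((yhat - y) / y))
  c(R2 = R2, RMSE = RMSE, MAPE = MAPE)
}

# --- [-1, 1] range scaler ----------------------------------------------------

#' Fit a min-max scaler mapping the training range onto [-1, 1]
#'
#' @param X training design matrix.
#' @param y optional training target.
#' @return A `range_scaler`.
#' @export
fit_scaler <- function(X, y = NULL) {
  X <- as.matrix(X)
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  out <- list(x_lo = lo, x_hi = hi)
  if (!is.null(y)) {
    out$y_lo <- min(y); out$y_hi <- max(y)
  }
  structure(out, class = "range_scaler")
}

scale_x <- function(scaler, X) {
  X <- as.matrix(X)
  span <- scaler$x_hi - scaler$x_lo
  span[span < 1e-12] <- 1      # constant columns map to -1; harmless
  sweep(sweep(X, 2, scaler$x_lo), 2, span, "/") * 2 - 1
}

scale_y <- function(scaler, y) {
  span <- scaler$y_hi - scaler$y_lo
  if (span < 1e-12) span <- 1
  (y - scaler$y_lo) / span * 2 - 1
}

unscale_y <- function(scaler, ys) {
  span <- scaler$y_hi - scaler$y_lo
  if (span < 1e-12) span <- 1
  (ys + 1) / 2 * span + scaler$y_lo
}

# --- fold-hygiene audit ------------------------------------------------------

# Every model fit records the sample indices it trained on (when an index
# mapping is active), so tests can verify that no fit ever saw held-out
# rows.
.audit_env <- new.env(parent = emptyenv())

#' Start recording fit audit events
#' @return NULL, invisibly.
#' @export
audit_start <- function() {
  .audit_env$log <- list()
  .audit_env$active <- TRUE
  invisible(NULL)
}

#' Stop recording and return the audit log
#' @return List of events: `stage` label and `indices` trained on.
#' @export
audit_stop <- function() {
  log <- .audit_env$log %||% list()
  .audit_env$active <- FALSE
  .audit_env$log <- list()
  log
}

audit_record <- function(stage, indices) {
  if (isTRUE(.audit_env$active) && !is.null(indices)) {
    .audit_env$log[[length(.audit_env$log) + 1L]] <-
      list(stage = stage, indices = indices)
  }
  invisible(NULL)
}
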