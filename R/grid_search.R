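# Exhaustive cross-validated grid search.

#' Cross-validated grid search over a hyperparameter grid
#'
#' Traverses every grid cell, evaluates it by k-fold cross-validation on
#' `(X, y)` (scalers refit per fold inside [train_model()]), and selects
#' the cell with the highest mean R2; ties break by lower mean RMSE, then
#' first-in-grid order.
#'
#' @param family model family (see [model_spec()]).
#' @param X design matrix.
#' @param y target vector.
#' @param grid list of parameter lists; defaults to [default_grid()].
#' @param k folds.
#' @param seed seed for the fold split and stochastic fits.
#' @param sample_indices optional enclosing-dataset indices for the
#'   fold-hygiene audit log.
#' @return A list: `best_params`, `best_index`, `cv` (per-cell mean
#'   metrics data frame).
#' @export
grid_search <- function(family, X, y, grid = default_grid(family),
                        k = 5L, seed = 1L, sample_indices = NULL) {
  if (length(grid) == 0) stop("empty grid", call. = FALSE)
  X <- as.matrix(X)
  n <- nrow(X)
  folds <- kfold_split(n, k, seed)
  if (is.null(sample_indices)) sample_indices <- seq_len(n)

  cell_metrics <- lapply(grid, function(cell) {
    per_fold <- vapply(folds, function(test) {
      train <- setdiff(seq_len(n), test)
      fit <- train_model(model_spec(family, cell, seed = seed),
                         X[train, , drop = FALSE], y[train],
                         sample_indices = sample_indices[train])
      regression_metrics(y[test], predict(fit, X[test, , drop = FALSE]))
    }, numeric(3))
    rowMeans(per_fold)
  })
  cv <- do.call(rbind, cell_metrics)
  cv <- data.frame(cell = seq_along(grid), cv)

  # best mean R2, tie -> lower RMSE, tie -> grid order
  ord <- order(-cv$R2, cv$RMSE, cv$cell)
  best <- ord[1]
  list(best_params = grid[[best]], best_index = best, cv = cv)
}
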