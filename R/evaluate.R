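# Cross-validated evaluation of one (input variant, model) cell.
#
# Fold discipline: selectors (Pearson screen, blockwise PCA), scalers and
# grid choices are refit inside every training fold by default; nothing
# fitted ever sees held-out rows. An optional mode instead fits the
# selectors once on the full data before cross-validation, matching a
# selection-before-modelling workflow.

#' Evaluate a model family (or the stacking model) on an input variant
#'
#' Runs k-fold cross-validation over the samples. Per outer fold:
#' selectors are fitted on the training rows ([fit_selectors()]), the
#' variant design is assembled for train and test, hyperparameters are
#' chosen by inner [grid_search()] on the training rows (or
#' [stacking_fit()] for `"SFM"`), and held-out metrics are computed in the
#' target's original units.
#'
#' @param table full 29-column feature table.
#' @param y target vector (leaf N content).
#' @param variant one of [variant_names()].
#' @param model a family name (`"MLR"`, `"PLS"`, `"SVR"`, `"BPNN"`,
#'   `"RF"`) or `"SFM"`.
#' @param k outer folds.
#' @param seed seed for folds, grids and stochastic fits.
#' @param threshold Pearson screening threshold.
#' @param grid optional hyperparameter grid for single families.
#' @param stack a [stack_spec()] (used when `model = "SFM"`).
#' @param prefit_selectors fit selectors once on the full data instead of per
#'   fold.
#' @param folds optional explicit list of held-out index sets, overriding
#'   the seeded [kfold_split()] (e.g. to hold folds fixed under a sample
#'   permutation).
#' @return A `cv_result`: `per_fold` metrics, `mean` metrics, `oof`
#'   out-of-fold predictions, `chosen` hyperparameters per fold, `variant`,
#'   `model`.
#' @export
evaluate_variant <- function(table, y, variant, model, k = 5L, seed = 1L,
                             threshold = 0.7, grid = NULL,
                             stack = stack_spec(k = k), prefit_selectors = FALSE,
                             folds = NULL) {
  stopifnot(nrow(table) == length(y))
  n <- length(y)
  if (is.null(folds)) folds <- kfold_split(n, k, seed) else k <- length(folds)
  full_sel <- if (prefit_selectors) fit_selectors(table, y, threshold) else NULL

  oof <- rep(NA_real_, n)
  per_fold <- matrix(NA_real_, k, 3, dimnames = list(NULL, c("R2", "RMSE", "MAPE")))
  chosen <- vector("list", k)

  for (f in seq_len(k)) {
    test <- folds[[f]]
    if (length(test) < 2) stop("fold with fewer than 2 test samples", call. = FALSE)
    train <- setdiff(seq_len(n), test)

    sel <- full_sel %||% fit_selectors(table[train, , drop = FALSE], y[train], threshold)
    Xtr <- assemble_variant(variant, table[train, , drop = FALSE], sel)$X
    Xte <- assemble_variant(variant, table[test, , drop = FALSE], sel)$X

    if (identical(model, "SFM")) {
      fit <- stacking_fit(Xtr, y[train], spec = stack, seed = seed,
                          sample_indices = train)
      chosen[[f]] <- fit$best_params
    } else {
      g <- grid %||% default_grid(model)
      if (length(g) > 1L) {
        gs <- grid_search(model, Xtr, y[train], grid = g, k = min(k, length(train)),
                          seed = seed, sample_indices = train)
        pars <- gs$best_params
      } else {
        pars <- g[[1]]
      }
      chosen[[f]] <- pars
      fit <- train_model(model_spec(model, pars, seed = seed), Xtr, y[train],
                         sample_indices = train)
    }
    pred <- predict(fit, Xte)
    oof[test] <- pred
    per_fold[f, ] <- regression_metrics(y[test], pred)
  }

  structure(list(per_fold = as.data.frame(per_fold),
                 mean = colMeans(per_fold),
                 oof = oof, chosen = chosen,
                 variant = variant, model = model, k = k, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s / %s (k = %d): R2 = %.4f, RMSE = %.4f, MAPE = %.4f\n",
              x$variant, x$model, x$k, x$mean["R2"], x$mean["RMSE"], x$mean["MAPE"]))
  invisible(x)
}
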