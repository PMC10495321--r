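# Stacking fusion model (SFM): a two-layer ensemble whose first layer
# stacks the out-of-fold (OOF) predictions of several base learners into
# an (m, p) meta-feature matrix (m samples, p bases), and whose second
# layer is a BPNN trained on those meta-features. At inference time the
# bases are refit on all training data and their predictions feed the
# meta-learner.

#' Stacking specification
#'
#' @param base_families character vector of base-learner families
#'   (default PLS, SVR, BPNN).
#' @param base_grids named list of grids per base family; defaults to
#'   [default_grid()] of each.
#' @param meta_params BPNN parameter list for the meta-learner.
#' @param k folds for the OOF construction and base grid searches.
#' @return A `stack_spec`.
#' @export
stack_spec <- function(base_families = c("PLS", "SVR", "BPNN"),
                       base_grids = NULL, meta_params = list(hidden = 10L),
                       k = 5L) {
  if (length(base_families) < 2) stop("need at least 2 base learners", call. = FALSE)
  if (is.null(base_grids)) {
    base_grids <- lapply(base_families, default_grid)
    names(base_grids) <- base_families
  }
  structure(list(base_families = base_families, base_grids = base_grids,
                 meta_params = meta_params, k = as.integer(k)),
            class = "stack_spec")
}

#' Fit a stacking fusion model
#'
#' For each of `k` folds, each base learner (with hyperparameters selected
#' by [grid_search()] on the full `(X, y)` passed here) is trained on the
#' other folds and predicts the held-out fold, yielding the `(m, p)` OOF
#' meta-feature matrix. The meta BPNN is trained on OOF -> y; bases are
#' then refit on all of `(X, y)` for inference.
#'
#' @param X training design matrix.
#' @param y training target.
#' @param spec a [stack_spec()].
#' @param seed seed for folds, grid searches and stochastic fits.
#' @param sample_indices optional enclosing-dataset indices for the audit
#'   log.
#' @return An `sfm_model`: fitted bases, meta-learner, OOF matrix,
#'   selected base hyperparameters.
#' @export
stacking_fit <- function(X, y, spec = stack_spec(), seed = 1L,
                         sample_indices = NULL) {
  stopifnot(inherits(spec, "stack_spec"))
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2 * spec$k) stop("need n >= 2k for stacking", call. = FALSE)
  if (is.null(sample_indices)) sample_indices <- seq_len(n)
  folds <- kfold_split(n, spec$k, seed)
  p <- length(spec$base_families)

  best <- vector("list", p)
  oof <- matrix(NA_real_, n, p, dimnames = list(NULL, spec$base_families))
  for (b in seq_len(p)) {
    fam <- spec$base_families[b]
    gs <- tryCatch(
      grid_search(fam, X, y, grid = spec$base_grids[[fam]], k = spec$k,
                  seed = seed, sample_indices = sample_indices),
      error = function(e) stop(sprintf("base learner %s failed: %s", fam,
                                       conditionMessage(e)), call. = FALSE))
    best[[b]] <- gs$best_params
    for (f in folds) {
      train <- setdiff(seq_len(n), f)
      fit <- train_model(model_spec(fam, gs$best_params, seed = seed),
                         X[train, , drop = FALSE], y[train],
                         sample_indices = sample_indices[train])
      oof[f, b] <- predict(fit, X[f, , drop = FALSE])
    }
  }

  meta <- train_model(model_spec("BPNN", spec$meta_params, seed = seed),
                      oof, y, sample_indices = sample_indices)

  bases <- lapply(seq_len(p), function(b) {
    train_model(model_spec(spec$base_families[b], best[[b]], seed = seed),
                X, y, sample_indices = sample_indices)
  })
  names(bases) <- spec$base_families

  structure(list(spec = spec, bases = bases, meta = meta, oof = oof,
                 best_params = stats::setNames(best, spec$base_families)),
            class = "sfm_model")
}

#' Predict from a stacking fusion model
#' @param object an `sfm_model`.
#' @param newdata design matrix.
#' @param ... unused.
#' @return Numeric predictions.
#' @export
predict.sfm_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  meta_X <- vapply(object$bases, function(b) predict(b, X), numeric(nrow(X)))
  if (nrow(X) == 1L) meta_X <- matrix(meta_X, nrow = 1)
  colnames(meta_X) <- object$spec$base_families
  predict(object$meta, meta_X)
}
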