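# Feature selection: Pearson screening and blockwise PCA with Kaiser
# retention.
#
# Two routes feed the regression layer: the strongly-correlated-term (SCT)
# sets, |r| > 0.7 against N, and blockwise principal-component scores where
# the colour and texture blocks are standardised and reduced separately,
# then concatenated.

#' Pearson screening of features against the target
#'
#' Sample Pearson correlation per column; selection keeps features with
#' `|r| > threshold`. Constant columns get `r = 0` and a flag.
#'
#' @param table feature data frame or matrix (`n x d`).
#' @param y numeric target, length `n`, non-constant.
#' @param threshold absolute-correlation selection threshold.
#' @return A `correlation_report`: data frame `feature`, `r`, `selected`,
#'   `constant`, plus the threshold.
#' @export
pearson_screen <- function(table, y, threshold = 0.7) {
  X <- as.matrix(table)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  if (stats::sd(y) < 1e-12) stop("`y` is constant", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  constant <- sds < 1e-12
  r <- rep(0, ncol(X))
  r[!constant] <- as.numeric(stats::cor(X[, !constant, drop = FALSE], y))
  rep_df <- data.frame(feature = colnames(X), r = r,
                       selected = abs(r) > threshold & !constant,
                       constant = constant, stringsAsFactors = FALSE)
  structure(list(report = rep_df, threshold = threshold),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("<correlation_report> threshold |r| > %g: %d of %d selected\n",
              x$threshold, sum(x$report$selected), nrow(x$report)))
  invisible(x)
}

#' Selected feature names of a correlation report
#' @param report a `correlation_report`.
#' @return Character vector.
#' @export
selected_features <- function(report) {
  stopifnot(inherits(report, "correlation_report"))
  report$report$feature[report$report$selected]
}

#' Standardised PCA of a feature block
#'
#' Columns are standardised (constant columns dropped with a warning) and
#' the correlation matrix eigendecomposed. Eigenvalues and cumulative
#' variance contribution rates (CVCR, %) follow the usual variance-table
#' semantics. Sign convention: each loading vector's largest-magnitude
#' entry is positive.
#'
#' @param table feature data frame or matrix (`n x d`, `n > 1`).
#' @param block label for bookkeeping (e.g. `"CF"`, `"TF"`).
#' @return A `pca_model`: `block`, `features`, `center`, `scale`,
#'   `loadings`, `eigenvalues`, `vcr`, `cvcr`, `k_retained` (Kaiser).
#' @export
fit_pca <- function(table, block = "block") {
  X <- as.matrix(table)
  if (nrow(X) < 2) stop("need n > 1 for PCA", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (all(sds < 1e-12)) stop("all columns are constant", call. = FALSE)
  if (any(sds < 1e-12)) {
    warning(sprintf("dropping %d constant column(s) from block %s",
                    sum(sds < 1e-12), block))
    X <- X[, sds >= 1e-12, drop = FALSE]
  }
  if (nrow(X) <= ncol(X)) {
    warning(sprintf("block %s is rank deficient (n <= d); proceeding", block))
  }
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  Z <- scale(X, center = ctr, scale = scl)
  C <- stats::cor(X)
  eig <- eigen(C, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  V <- eig$vectors
  for (k in seq_len(ncol(V))) {
    if (V[which.max(abs(V[, k])), k] < 0) V[, k] <- -V[, k]
  }
  rownames(V) <- colnames(X)
  vcr <- ev / sum(ev) * 100
  structure(list(block = block, features = colnames(X),
                 center = ctr, scale = scl, loadings = V,
                 eigenvalues = ev, vcr = vcr, cvcr = cumsum(vcr),
                 k_retained = kaiser_retain(ev, quiet = TRUE)),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> block %s: %d features, %d PCs retained (Kaiser)\n",
              x$block, length(x$features), x$k_retained))
  invisible(x)
}

#' Variance-table view of a PCA model
#'
#' @param model a `pca_model`.
#' @param n_pc number of leading components to show.
#' @return Data frame `block`, `PC`, `eigenvalue`, `VCR`, `CVCR`.
#' @export
pca_table <- function(model, n_pc = 5L) {
  stopifnot(inherits(model, "pca_model"))
  k <- min(n_pc, length(model$eigenvalues))
  data.frame(block = model$block, PC = seq_len(k),
             eigenvalue = model$eigenvalues[seq_len(k)],
             VCR = model$vcr[seq_len(k)], CVCR = model$cvcr[seq_len(k)])
}

#' Kaiser retention rule
#'
#' Number of eigenvalues exceeding 1; if none do, one component is
#' retained with a warning.
#'
#' @param eigenvalues nonincreasing, nonnegative numeric vector.
#' @param quiet suppress the floor warning.
#' @return Integer `k >= 1`.
#' @export
kaiser_retain <- function(eigenvalues, quiet = FALSE) {
  if (length(eigenvalues) == 0) stop("empty eigenvalue vector", call. = FALSE)
  k <- sum(eigenvalues > 1)
  if (k == 0) {
    if (!quiet) warning("no eigenvalue exceeds 1; retaining one component")
    k <- 1L
  }
  as.integer(k)
}

#' Project data onto a fitted PCA model
#'
#' Standardises by the model's training means/SDs and projects onto the
#' retained loadings.
#'
#' @param model a `pca_model`.
#' @param table data with (at least) the model's feature columns.
#' @param k number of components; defaults to the model's Kaiser retention.
#' @return `n x k` score matrix, columns `<block>PC1..k`.
#' @export
pca_transform <- function(model, table, k = model$k_retained) {
  stopifnot(inherits(model, "pca_model"))
  X <- as.matrix(table)
  missing <- setdiff(model$features, colnames(X))
  if (length(missing)) {
    stop(sprintf("missing feature column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  X <- X[, model$features, drop = FALSE]
  Z <- scale(X, center = model$center, scale = model$scale)
  S <- Z %*% model$loadings[, seq_len(k), drop = FALSE]
  colnames(S) <- paste0(model$block, "PC", seq_len(k))
  S
}

# --- input-variant assembly --------------------------------------------------

.variant_names <- c("CF-SCT", "TF-SCT", "CTIF-SCT", "CF-PCA", "TF-PCA", "C-T-PCA")

#' The six model-input variant names
#' @return Character vector.
#' @export
variant_names <- function() .variant_names

#' Fit the feature selectors on (training) data
#'
#' Runs the Pearson screen on all features and fits one PCA model per
#' block (colour, texture). Fit this on training folds only and reuse it
#' via [assemble_variant()] on held-out data.
#'
#' @param table full 29-column feature table.
#' @param y target vector.
#' @param threshold screening threshold on `|r|`.
#' @return A `selector_set`: `screen`, `pca_cf`, `pca_tf`.
#' @export
fit_selectors <- function(table, y, threshold = 0.7) {
  cf <- intersect(color_feature_names(), colnames(table))
  tf <- intersect(texture_feature_names(), colnames(table))
  structure(list(
    screen = pearson_screen(table, y, threshold),
    pca_cf = fit_pca(table[, cf, drop = FALSE], block = "CF"),
    pca_tf = fit_pca(table[, tf, drop = FALSE], block = "TF")
  ), class = "selector_set")
}

#' Assemble a model-input variant
#'
#' SCT variants select screened raw features (`CTIF-SCT` is the union of
#' the colour and texture survivors); PCA variants use Kaiser-retained
#' blockwise scores (`C-T-PCA` concatenates the colour-block and
#' texture-block scores).
#'
#' @param name one of [variant_names()].
#' @param table feature table to transform (train or test rows).
#' @param selectors a `selector_set` fitted on training data.
#' @return An `input_variant`: `name`, `X` (design matrix), `provenance`.
#' @export
assemble_variant <- function(name, table, selectors) {
  stopifnot(inherits(selectors, "selector_set"))
  name <- match.arg(name, .variant_names)
  sel <- selected_features(selectors$screen)
  cf_sel <- intersect(sel, color_feature_names())
  tf_sel <- intersect(sel, texture_feature_names())

  pick <- function(cols, tag) {
    if (length(cols) == 0) {
      stop(sprintf("variant %s: empty feature selection", name), call. = FALSE)
    }
    X <- as.matrix(table[, cols, drop = FALSE])
    list(X = X, prov = paste0(tag, ":", cols))
  }

  out <- switch(name,
    "CF-SCT" = pick(cf_sel, "CF"),
    "TF-SCT" = pick(tf_sel, "TF"),
    "CTIF-SCT" = pick(c(cf_sel, tf_sel), "C-TIF"),
    "CF-PCA" = {
      S <- pca_transform(selectors$pca_cf, table)
      list(X = S, prov = colnames(S))
    },
    "TF-PCA" = {
      S <- pca_transform(selectors$pca_tf, table)
      list(X = S, prov = colnames(S))
    },
    "C-T-PCA" = {
      S <- cbind(pca_transform(selectors$pca_cf, table),
                 pca_transform(selectors$pca_tf, table))
      list(X = S, prov = colnames(S))
    })
  structure(list(name = name, X = out$X, provenance = out$prov),
            class = "input_variant")
}
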