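# Experiment orchestration: generate -> preprocess -> extract -> select ->
# train -> report over the full stage x variant x model matrix.

#' Experiment configuration
#'
#' All randomness is funnelled through a single seed: the generator, fold
#' splits and model initialisations derive their seeds from it, so a rerun
#' with the same configuration reproduces the leaderboard.
#'
#' @param stages growth stages to simulate.
#' @param n_samples samples per stage.
#' @param image_size image dimensions `(H, W)`.
#' @param generator_args extra arguments passed to [generator_config()]
#'   (e.g. `color_noise_sd`, `illumination`).
#' @param msrcr_correct apply MSRCR before extraction.
#' @param msrcr_pars an [msrcr_params()].
#' @param masks `"segment"` or `"true"` (generator ground truth).
#' @param levels GLCM gray levels.
#' @param threshold Pearson screening threshold.
#' @param variants input variants to run (subset of [variant_names()]).
#' @param models model list (families and/or `"SFM"`).
#' @param k cross-validation folds.
#' @param seed master seed.
#' @param out_dir optional directory for artifacts (images, masks,
#'   features.csv, selection tables, results JSON).
#' @return An `experiment_config`.
#' @export
experiment_config <- function(stages = c("tillering", "elongation"),
                              n_samples = 60L,
                              image_size = c(256L, 256L),
                              generator_args = list(),
                              msrcr_correct = TRUE,
                              msrcr_pars = msrcr_params(),
                              masks = c("segment", "true"),
                              levels = 64L,
                              threshold = 0.7,
                              variants = variant_names(),
                              models = c("MLR", "PLS", "SVR", "BPNN", "RF", "SFM"),
                              k = 5L, seed = 1L, out_dir = NULL) {
  masks <- match.arg(masks)
  stopifnot(all(variants %in% variant_names()))
  if (length(models) == 0) stop("empty model list", call. = FALSE)
  ok <- models %in% c("MLR", "PLS", "SVR", "BPNN", "RF", "SFM")
  if (!all(ok)) stop(sprintf("unknown model(s): %s",
                             paste(models[!ok], collapse = ", ")), call. = FALSE)
  structure(list(stages = stages, n_samples = as.integer(n_samples),
                 image_size = as.integer(image_size),
                 generator_args = generator_args,
                 msrcr_correct = isTRUE(msrcr_correct), msrcr_pars = msrcr_pars,
                 masks = masks, levels = as.integer(levels),
                 threshold = threshold, variants = variants, models = models,
                 k = as.integer(k), seed = as.integer(seed), out_dir = out_dir),
            class = "experiment_config")
}

#' Deterministic fingerprint of an experiment configuration
#'
#' MD5 of the serialised configuration; identical configurations hash
#' identically, any field change alters the hash. Used for the provenance
#' block of [run_experiment()] reports.
#'
#' @param config an [experiment_config()].
#' @return A 32-character hash string.
#' @export
config_hash <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(config, NULL, version = 2), f)
  unname(tools::md5sum(f))
}

#' Run the full estimation experiment
#'
#' Per stage: generates the synthetic dataset, preprocesses (MSRCR and
#' masking), extracts the 29-feature table, fits the selection layer for
#' reporting (correlation report, variance tables), then evaluates every
#' variant x model cell with [evaluate_variant()]. Cell failures are
#' recorded and the run continues.
#'
#' @param config an [experiment_config()].
#' @return An `experiment_report`: `leaderboard` data frame, per-stage
#'   `pca_tables`, `correlation`, `features`, `cv` results, `failures`,
#'   and the `config`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  seeds <- derive_seeds(config$seed, length(config$stages) + 1L)
  model_seed <- seeds[length(seeds)]

  leaderboard <- list(); cvs <- list(); failures <- list()
  pca_tables <- list(); correlation <- list(); features <- list()

  for (si in seq_along(config$stages)) {
    stage <- config$stages[si]
    gen_args <- c(list(n_samples = config$n_samples,
                       image_size = config$image_size,
                       stage = stage, seed = seeds[si]),
                  config$generator_args)
    dataset <- generate_dataset(do.call(generator_config, gen_args))
    ext <- dataset_features(dataset, msrcr_correct = config$msrcr_correct,
                            msrcr_pars = config$msrcr_pars,
                            masks = config$masks, levels = config$levels)
    features[[stage]] <- ext

    sel <- fit_selectors(ext$features, ext$n, config$threshold)
    correlation[[stage]] <- sel$screen
    pca_tables[[stage]] <- rbind(pca_table(sel$pca_cf), pca_table(sel$pca_tf))

    if (!is.null(config$out_dir)) {
      sdir <- file.path(config$out_dir, stage)
      dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
      write_dataset(dataset, file.path(sdir, "images"))
      utils::write.csv(cbind(sample = rownames(ext$features), ext$features,
                             n_value = ext$n),
                       file.path(sdir, "features.csv"), row.names = FALSE)
      utils::write.csv(sel$screen$report, file.path(sdir, "correlation.csv"),
                       row.names = FALSE)
      utils::write.csv(pca_tables[[stage]], file.path(sdir, "pca_table.csv"),
                       row.names = FALSE)
    }

    for (variant in config$variants) {
      for (model in config$models) {
        key <- paste(stage, variant, model, sep = "/")
        res <- tryCatch(
          evaluate_variant(ext$features, ext$n, variant, model,
                           k = config$k, seed = model_seed,
                           threshold = config$threshold),
          error = function(e) e)
        if (inherits(res, "error")) {
          failures[[key]] <- conditionMessage(res)
        } else {
          cvs[[key]] <- res
          leaderboard[[key]] <- data.frame(
            stage = stage, variant = variant, model = model,
            R2 = res$mean["R2"], RMSE = res$mean["RMSE"],
            MAPE = res$mean["MAPE"], row.names = NULL)
        }
      }
    }
  }

  lb <- do.call(rbind, leaderboard)
  rownames(lb) <- NULL
  provenance <- list(config_hash = config_hash(config), seed = config$seed,
                     package_version = as.character(utils::packageVersion("leafnitro")),
                     r_version = R.version.string)
  report <- structure(list(leaderboard = lb, pca_tables = pca_tables,
                           correlation = correlation, features = features,
                           cv = cvs, failures = failures, config = config,
                           provenance = provenance),
                      class = "experiment_report")
  if (!is.null(config$out_dir)) {
    utils::write.csv(lb, file.path(config$out_dir, "leaderboard.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      lapply(cvs, function(r) list(variant = r$variant, model = r$model,
                                   mean = as.list(r$mean),
                                   per_fold = r$per_fold)),
      file.path(config$out_dir, "results.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}

#' Summarise an experiment report
#'
#' Ranks variants within each model and models within each variant,
#' mirroring the two comparison axes of the experiment.
#'
#' @param report an `experiment_report` (or a directory containing a
#'   `leaderboard.csv` written by [run_experiment()]).
#' @return The leaderboard, sorted by stage and descending R2, invisibly;
#'   prints a readable summary.
#' @export
report_experiment <- function(report) {
  if (is.character(report)) {
    path <- file.path(report, "leaderboard.csv")
    if (!file.exists(path)) stop(sprintf("missing artifact: %s", path), call. = FALSE)
    lb <- utils::read.csv(path)
  } else {
    stopifnot(inherits(report, "experiment_report"))
    lb <- report$leaderboard
    if (length(report$failures)) {
      cat("failed cells:\n")
      for (k in names(report$failures)) cat("  ", k, ": ", report$failures[[k]], "\n")
    }
  }
  if (is.null(lb) || nrow(lb) == 0) stop("no completed cells to report", call. = FALSE)
  lb <- lb[order(lb$stage, -lb$R2), ]
  for (stage in unique(lb$stage)) {
    cat(sprintf("== %s ==\n", stage))
    sub <- lb[lb$stage == stage, ]
    for (i in seq_len(nrow(sub))) {
      cat(sprintf("  %-9s %-9s R2 = %6.4f  RMSE = %6.4f  MAPE = %6.4f\n",
                  sub$variant[i], sub$model[i], sub$R2[i], sub$RMSE[i], sub$MAPE[i]))
    }
  }
  invisible(lb)
}
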