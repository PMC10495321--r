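# Per-sample feature table assembly.

#' Extract the 29-column feature table for a set of samples
#'
#' Computes the 24 colour features and 5 direction-averaged texture
#' features per sample. Rows follow sample order; columns follow
#' [feature_names()].
#'
#' @param images list of [rgb_image()] objects.
#' @param masks list of `leaf_mask`/logical masks, aligned with `images`.
#' @param levels gray levels for the GLCM quantisation.
#' @param sample_ids optional row names; defaults to `S1, S2, ...`.
#' @return A data frame (`n x 29`) with `check.names = FALSE`.
#' @export
extract_features <- function(images, masks, levels = 64L, sample_ids = NULL) {
  if (length(images) != length(masks)) {
    stop("`images` and `masks` must be aligned lists", call. = FALSE)
  }
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_along(images))
  rows <- lapply(seq_along(images), function(i) {
    row <- tryCatch(
      c(color_features(images[[i]], masks[[i]]),
        texture_features(images[[i]], masks[[i]], levels = levels)),
      error = function(e) {
        stop(sprintf("feature extraction failed for sample '%s': %s",
                     sample_ids[i], conditionMessage(e)), call. = FALSE)
      })
    row
  })
  tab <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  names(tab) <- feature_names()
  rownames(tab) <- sample_ids
  tab
}

#' Feature table of a synthetic dataset
#'
#' Convenience wrapper: optionally MSRCR-corrects each image, obtains masks
#' by whiteboard segmentation or from the generator ground truth, and
#' extracts the feature table.
#'
#' @param dataset a `synthetic_dataset` from [generate_dataset()].
#' @param msrcr_correct logical: apply [msrcr()] before extraction.
#' @param msrcr_pars an [msrcr_params()].
#' @param masks `"segment"` (whiteboard segmentation) or `"true"`
#'   (generator ground truth).
#' @param levels gray levels for GLCM.
#' @return A list: `features` (data frame), `n` (latent N values),
#'   `masks` (list of `leaf_mask`).
#' @export
dataset_features <- function(dataset, msrcr_correct = TRUE,
                             msrcr_pars = msrcr_params(),
                             masks = c("segment", "true"), levels = 64L) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  masks <- match.arg(masks)
  imgs <- vector("list", length(dataset))
  mks <- vector("list", length(dataset))
  for (i in seq_along(dataset)) {
    img <- dataset[[i]]$image
    if (msrcr_correct) img <- msrcr(img, msrcr_pars)
    imgs[[i]] <- img
    mks[[i]] <- if (masks == "true") as_leaf_mask(dataset[[i]]$true_mask)
                else segment_leaf(img)
  }
  list(features = extract_features(imgs, mks, levels = levels),
       n = dataset_n_values(dataset),
       masks = mks)
}
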