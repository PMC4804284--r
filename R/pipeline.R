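#' Preprocess and featurize one image
#'
#' Convenience wrapper: illumination correction, nucleus segmentation,
#' per-pixel feature maps and per-nucleus summaries for a single stack.
#' Feature columns are raw (not standardized); standardize across an image
#' set with [scale_per_image()].
#'
#' @param stack An uncorrected (or corrected) [channel_stack()].
#' @param pre_cfg A [preprocess_config()].
#' @param feat_cfg A [feature_config()].
#' @return A list with `stack` (corrected), `nuclei` (records) and
#'   `features` (raw per-nucleus data frame), or `NULL` features when no
#'   nuclei were found.
#' @export
process_image <- function(stack, pre_cfg = preprocess_config(),
                          feat_cfg = feature_config()) {
  if (!stack$corrected) stack <- correct_illumination(stack, pre_cfg)
  nuclei <- segment_nuclei(stack, pre_cfg)
  features <- if (length(nuclei) > 0) {
    maps <- pixel_feature_maps(stack, feat_cfg)
    featurize_nuclei(maps, nuclei, feat_cfg)
  } else NULL
  list(stack = stack, nuclei = nuclei, features = features)
}

#' Process a synthetic dataset into a labeled feature table
#'
#' Runs [process_image()] on every scene of an [generate_dataset()] output,
#' standardizes features per image, and labels segmented nuclei by matching
#' the ground-truth target centers as annotation dots.
#'
#' @param dataset An `nq_dataset`.
#' @param pre_cfg,feat_cfg Configurations.
#' @param radius Dot-matching radius (pixels) used for labeling.
#' @return A list with `features` (standardized, pooled), `labels` (pooled
#'   [match_annotations()] output), `nuclei` (named list of record lists
#'   per image) and `stacks` (corrected stacks per image).
#' @export
process_dataset <- function(dataset, pre_cfg = preprocess_config(),
                            feat_cfg = feature_config(), radius = 15) {
  stopifnot(inherits(dataset, "nq_dataset"))
  feats <- list(); labs <- list(); nucs <- list(); stacks <- list()
  for (sc in dataset$scenes) {
    res <- process_image(sc$stack, pre_cfg, feat_cfg)
    img <- sc$stack$image_id
    tr <- sc$truth[sc$truth$is_target, c("row", "col")]
    labs[[img]] <- match_annotations(res$nuclei, tr, radius)
    feats[[img]] <- res$features
    nucs[[img]] <- res$nuclei
    stacks[[img]] <- res$stack
  }
  list(features = scale_per_image(do.call(rbind, feats)),
       labels = do.call(rbind, labs), nuclei = nucs, stacks = stacks)
}
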