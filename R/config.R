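#' Preprocessing configuration
#'
#' Parameters controlling illumination correction and nucleus segmentation.
#'
#' @param background_sigma Scale (pixels) of the Gaussian blur of the
#'   structural channel used as the local background estimate. Default 10.
#' @param min_nucleus_area Minimum connected-component area (pixels) kept as
#'   a nucleus; components strictly smaller are discarded as noise.
#'   Default 5.
#' @param connectivity Pixel connectivity for component labeling, 4 or 8.
#'   Default 8.
#' @param background_floor_epsilon Fraction of the maximum background used
#'   to floor the divisor in illumination correction; pixels whose
#'   background falls at or below the floor are set to 0. Default 1e-3.
#' @return A list of class `nq_preprocess_config`.
#' @export
preprocess_config <- function(background_sigma = 10, min_nucleus_area = 5,
                              connectivity = 8,
                              background_floor_epsilon = 1e-3) {
  stopifnot(background_sigma > 0, min_nucleus_area >= 1,
            connectivity %in% c(4, 8), background_floor_epsilon >= 0)
  structure(list(background_sigma = background_sigma,
                 min_nucleus_area = min_nucleus_area,
                 connectivity = as.integer(connectivity),
                 background_floor_epsilon = background_floor_epsilon),
            class = "nq_preprocess_config")
}

#' Feature-extraction configuration
#'
#' Free parameters of the five per-pixel feature families and of the
#' per-nucleus summaries. Defaults are sized for nuclei of roughly 5-15 px
#' radius, as in 40x confocal tissue images.
#'
#' @param hog_max_order Highest angular Fourier order of the gradient
#'   orientation histogram (orders 0..`hog_max_order` are emitted).
#' @param hog_radial_sigmas Radial Gaussian scales (pixels) over which the
#'   angular moments are pooled.
#' @param haralick_window Odd side length (pixels) of the sliding window on
#'   which gray-level co-occurrence statistics are computed.
#' @param haralick_levels Number of gray levels the intensity range is
#'   quantized into (equal-width bins over the per-image range).
#' @param haralick_offsets Integer matrix of (dr, dc) co-occurrence
#'   displacements; statistics are averaged over offsets. Default:
#'   distance-1 in 4 directions.
#' @param entropy_window Odd side length (pixels) of the local entropy
#'   window.
#' @param entropy_bins Histogram bins for local entropy.
#' @param ridge_sigma Scale (pixels) of the steerable
#'   second-derivative-of-Gaussian ridge filter.
#' @param voting_sigma Scale (pixels) of the stick tensor-voting field.
#' @param vote_rel_threshold Ridge strength (fraction of the image maximum)
#'   below which pixels do not cast votes; limits voting cost, negligible
#'   responses contribute next to nothing to the accumulated tensor.
#' @param ecs_threshold_method Thresholding method for the tissue mask used
#'   by the extracellular-component-size map; only `"otsu"` is available.
#' @param ring_radius Radius (pixels) of the perinuclear ring (dilation of
#'   the nucleus minus the nucleus) used as the "surroundings" region.
#'   Default 15, the radius bound used to match annotation dots to nuclei.
#' @return A list of class `nq_feature_config`.
#' @export
feature_config <- function(hog_max_order = 4, hog_radial_sigmas = c(2, 4, 8),
                           haralick_window = 15, haralick_levels = 8,
                           haralick_offsets = rbind(c(0, 1), c(1, 0),
                                                    c(1, 1), c(1, -1)),
                           entropy_window = 9, entropy_bins = 32,
                           ridge_sigma = 2, voting_sigma = 10,
                           vote_rel_threshold = 0.1,
                           ecs_threshold_method = "otsu", ring_radius = 15) {
  stopifnot(hog_max_order >= 1, all(hog_radial_sigmas > 0),
            haralick_window >= 3, haralick_window %% 2 == 1,
            haralick_levels >= 2, is.matrix(haralick_offsets),
            ncol(haralick_offsets) == 2,
            entropy_window >= 3, entropy_window %% 2 == 1, entropy_bins >= 2,
            ridge_sigma > 0, voting_sigma > 0, ring_radius >= 1)
  ecs_threshold_method <- match.arg(ecs_threshold_method, "otsu")
  structure(list(hog_max_order = as.integer(hog_max_order),
                 hog_radial_sigmas = hog_radial_sigmas,
                 haralick_window = as.integer(haralick_window),
                 haralick_levels = as.integer(haralick_levels),
                 haralick_offsets = matrix(as.integer(haralick_offsets),
                                           ncol = 2),
                 entropy_window = as.integer(entropy_window),
                 entropy_bins = as.integer(entropy_bins),
                 ridge_sigma = ridge_sigma, voting_sigma = voting_sigma,
                 vote_rel_threshold = vote_rel_threshold,
                 ecs_threshold_method = ecs_threshold_method,
                 ring_radius = as.integer(ring_radius)),
            class = "nq_feature_config")
}

#' Read a pipeline configuration file
#'
#' Reads a JSON or YAML file that may contain `channel_map` (role -> channel
#' index), `preprocess` and `features` sections; missing sections fall back
#' to package defaults.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A list with elements `channel_map`, `preprocess` and `features`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                yaml = ,
                yml = yaml::read_yaml(path),
                stop("unsupported config format: .", ext))
  cm <- raw$channel_map
  if (!is.null(cm)) cm <- unlist(cm)
  pre <- do.call(preprocess_config, as.list(raw$preprocess))
  fl <- as.list(raw$features)
  if (!is.null(fl$haralick_offsets)) {
    fl$haralick_offsets <- matrix(unlist(fl$haralick_offsets),
                                  ncol = 2, byrow = TRUE)
  }
  feat <- do.call(feature_config, fl)
  list(channel_map = cm, preprocess = pre, features = feat)
}
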