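#' Synthetic tissue-scene specification
#'
#' Describes a multi-channel synthetic tissue image: elliptical DAPI-like
#' nuclei, striated high-intensity structural texture (sarcomere-like
#' banding) in a disk around each target ("myocyte-like") nucleus, diffuse
#' interstitial structural background, marker-positive nuclear subsets, a
#' smooth multiplicative illumination gain, and additive Gaussian noise.
#' Defaults emulate a 40x confocal field with about 150 nuclei of which
#' 30% are targets.
#'
#' @param height,width Field size in pixels.
#' @param n_target_nuclei,n_other_nuclei Numbers of target and non-target
#'   nuclei.
#' @param nucleus_radius_range Range (pixels) of the ellipse semi-major
#'   axis; the aspect ratio is sampled in \[1, 2\] with the semi-minor
#'   axis kept at >= 2 px so nuclei survive the area-5 noise filter by
#'   construction.
#' @param striation_radius Radius (pixels) of the striated disk painted
#'   around each target nucleus.
#' @param striation_period Stripe period in pixels (sarcomere-like
#'   banding).
#' @param striation_amplitude Peak-to-trough stripe amplitude (intensity).
#' @param interstitial_background_level Diffuse structural intensity away
#'   from striation.
#' @param marker_positive_fraction_target,marker_positive_fraction_other
#'   Fractions of each class painted marker-positive (planted exactly,
#'   rounded to counts).
#' @param illumination_gain One of `"none"`, `"linear"`, `"radial"`.
#' @param gain_strength Maximum/minimum gain ratio of the field.
#' @param noise_sigma Additive Gaussian noise level (clipped at 0).
#' @param min_center_separation Minimum distance between nucleus centers.
#' @param seed Integer seed; all scene randomness flows from it.
#' @return A list of class `nq_scene_spec`.
#' @export
scene_spec <- function(height = 512, width = 512, n_target_nuclei = 45,
                       n_other_nuclei = 105, nucleus_radius_range = c(4, 7),
                       striation_radius = 20, striation_period = 6,
                       striation_amplitude = 0.5,
                       interstitial_background_level = 0.25,
                       marker_positive_fraction_target = 0.2,
                       marker_positive_fraction_other = 0.05,
                       illumination_gain = c("none", "linear", "radial"),
                       gain_strength = 2, noise_sigma = 0.02,
                       min_center_separation = 24, seed = 1) {
  illumination_gain <- match.arg(illumination_gain)
  stopifnot(n_target_nuclei >= 0, n_other_nuclei >= 0,
            min(nucleus_radius_range) >= 2,
            marker_positive_fraction_target >= 0,
            marker_positive_fraction_target <= 1,
            marker_positive_fraction_other >= 0,
            marker_positive_fraction_other <= 1,
            noise_sigma >= 0, gain_strength >= 1)
  structure(as.list(environment()), class = "nq_scene_spec")
}

gain_field <- function(spec) {
  h <- spec$height; w <- spec$width
  switch(spec$illumination_gain,
         none = matrix(1, h, w),
         linear = matrix(rep(seq(1, spec$gain_strength, length.out = w),
                             each = h), h, w),
         radial = {
           r <- outer((seq_len(h) - h / 2)^2, (seq_len(w) - w / 2)^2, "+")
           rmax <- max(r)
           1 + (spec$gain_strength - 1) * (1 - r / rmax)
         })
}

#' Generate one synthetic tissue scene
#'
#' Places non-overlapping elliptical nuclei by rejection sampling, paints
#' the nuclear, structural and marker channels, applies the multiplicative
#' gain field to all channels, and adds seeded Gaussian noise clipped at
#' zero. Deterministic given `spec$seed`.
#'
#' @param spec A [scene_spec()].
#' @param image_id Identifier given to the generated stack.
#' @return A list of class `nq_scene` with `stack` (an uncorrected
#'   [channel_stack()]) and `truth` (data frame `image_id`, `row`, `col`,
#'   `radius`, `is_target`, `is_marker_positive`).
#' @export
generate_scene <- function(spec, image_id = sprintf("scene%03d", spec$seed)) {
  stopifnot(inherits(spec, "nq_scene_spec"))
  h <- spec$height; w <- spec$width
  ntot <- spec$n_target_nuclei + spec$n_other_nuclei
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)

  margin <- max(spec$nucleus_radius_range) + 2
  centers <- matrix(NA_real_, 0, 2)
  attempts <- 0L
  max_attempts <- 400L * max(1L, ntot)
  while (nrow(centers) < ntot) {
    if (attempts >= max_attempts)
      stop("could not place ", ntot, " nuclei with separation ",
           spec$min_center_separation, " in a ", h, "x", w, " field")
    attempts <- attempts + 1L
    cand <- c(runif(1, margin, h - 1 - margin), runif(1, margin, w - 1 - margin))
    if (nrow(centers) == 0 ||
        min((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2) >=
        spec$min_center_separation^2) {
      centers <- rbind(centers, cand)
    }
  }
  is_target <- rep(FALSE, ntot)
  if (spec$n_target_nuclei > 0)
    is_target[sample.int(ntot, spec$n_target_nuclei)] <- TRUE
  a <- runif(ntot, spec$nucleus_radius_range[1], spec$nucleus_radius_range[2])
  aspect <- runif(ntot, 1, 2)
  b <- pmax(2, a / aspect)
  theta <- runif(ntot, 0, pi)
  stripe_dir <- runif(ntot, 0, pi)
  nuc_int <- pmax(0.3, rnorm(ntot, 0.7, 0.05))
  plant <- function(class_sel, frac) {
    ids <- which(class_sel)
    k <- round(frac * length(ids))
    flags <- rep(FALSE, ntot)
    if (k > 0) flags[sample(ids, k)] <- TRUE
    flags
  }
  is_marker <- plant(is_target, spec$marker_positive_fraction_target) |
    plant(!is_target, spec$marker_positive_fraction_other)

  rowg <- matrix(rep(0:(h - 1), w), h, w)
  colg <- matrix(rep(0:(w - 1), each = h), h, w)
  nuclear <- matrix(0.03, h, w)
  structural <- matrix(spec$interstitial_background_level, h, w) +
    0.3 * spec$interstitial_background_level *
      matrix(runif(h * w, -1, 1), h, w)
  marker <- matrix(0.02, h, w)
  nucleus_mask <- matrix(FALSE, h, w)

  ellipse_idx <- function(i) {
    dr <- rowg - centers[i, 1]
    dc <- colg - centers[i, 2]
    u <- dc * cos(theta[i]) + dr * sin(theta[i])
    v <- -dc * sin(theta[i]) + dr * cos(theta[i])
    which((u / a[i])^2 + (v / b[i])^2 <= 1)
  }
  # striated structural texture around target nuclei
  for (i in which(is_target)) {
    dr <- rowg - centers[i, 1]
    dc <- colg - centers[i, 2]
    disk <- dr^2 + dc^2 <= spec$striation_radius^2
    u <- dc * cos(stripe_dir[i]) + dr * sin(stripe_dir[i])
    stripes <- 0.3 + spec$striation_amplitude *
      0.5 * (1 + sin(2 * pi * u / spec$striation_period))
    structural[disk] <- pmax(structural[disk], stripes[disk])
  }
  for (i in seq_len(ntot)) {
    idx <- ellipse_idx(i)
    nuclear[idx] <- nuc_int[i]
    nucleus_mask[idx] <- TRUE
    if (is_marker[i]) marker[idx] <- 0.6
  }
  structural[nucleus_mask] <- 0.05  # nuclei displace the structural stain

  g <- gain_field(spec)
  noisy <- function(ch) {
    out <- ch * g + rnorm(h * w, 0, spec$noise_sigma)
    out[out < 0] <- 0
    out
  }
  stack <- channel_stack(nuclear = noisy(nuclear),
                         structural = noisy(structural),
                         marker = noisy(marker),
                         image_id = image_id, corrected = FALSE)
  truth <- data.frame(image_id = image_id, row = centers[, 1],
                      col = centers[, 2], radius = a,
                      is_target = is_target, is_marker_positive = is_marker)
  structure(list(stack = stack, truth = truth, spec = spec),
            class = "nq_scene")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate a multi-image synthetic dataset with simulated raters
#'
#' Generates `n_images` scenes from a template spec with per-image seeds
#' `base_seed + index`, plus simulated expert dot annotations: each rater
#' dots every true target nucleus with probability `hit_rate` (at the true
#' center plus Gaussian jitter) and each non-target nucleus with
#' probability `fp_rate`.
#'
#' @param spec Template [scene_spec()]; its `seed` field is overridden per
#'   image.
#' @param n_images Number of images (>= 2, so leave-image-out is possible).
#' @param base_seed Base seed for per-image seeds and rater simulation.
#' @param n_raters Number of simulated raters.
#' @param hit_rate,fp_rate Per-nucleus dot probabilities for targets and
#'   non-targets.
#' @param jitter_sd Standard deviation (pixels) of dot placement jitter.
#' @param dir Optional output directory; when given, writes per-image
#'   3-channel TIFFs (R = structural, G = marker, B = nuclear), a pooled
#'   `truth.csv`, per-rater dot CSVs (`rater<k>.csv` with `image_id`,
#'   `row`, `col`) and the spec as `spec.json`.
#' @return A list of class `nq_dataset` with `scenes` (list of
#'   `nq_scene`), `truth` (pooled data frame) and `rater_dots` (named list
#'   of data frames with `image_id`, `row`, `col`).
#' @export
generate_dataset <- function(spec, n_images = 8, base_seed = 1,
                             n_raters = 4, hit_rate = 0.9, fp_rate = 0.05,
                             jitter_sd = 2, dir = NULL) {
  stopifnot(inherits(spec, "nq_scene_spec"), n_images >= 2)
  scenes <- lapply(seq_len(n_images), function(i) {
    s <- spec
    s$seed <- base_seed + i
    generate_scene(s, image_id = sprintf("img%03d", i))
  })
  truth <- do.call(rbind, lapply(scenes, `[[`, "truth"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(base_seed)
  rater_dots <- lapply(seq_len(n_raters), function(r) {
    p <- ifelse(truth$is_target, hit_rate, fp_rate)
    dotted <- runif(nrow(truth)) < p
    data.frame(image_id = truth$image_id[dotted],
               row = truth$row[dotted] + rnorm(sum(dotted), 0, jitter_sd),
               col = truth$col[dotted] + rnorm(sum(dotted), 0, jitter_sd))
  })
  names(rater_dots) <- paste0("rater", seq_len(n_raters))
  ds <- structure(list(scenes = scenes, truth = truth,
                       rater_dots = rater_dots),
                  class = "nq_dataset")
  if (!is.null(dir)) write_dataset(ds, spec, dir)
  ds
}

write_dataset <- function(ds, spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sc in ds$scenes) {
    st <- sc$stack
    arr <- array(0, c(st$height, st$width, 3))
    arr[, , 1] <- pmin(st$structural, 1)
    arr[, , 2] <- pmin(st$marker, 1)
    arr[, , 3] <- pmin(st$nuclear, 1)
    tiff::writeTIFF(arr, file.path(dir, paste0(st$image_id, ".tif")),
                    bits.per.sample = 32L)
  }
  write.csv(ds$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  for (r in names(ds$rater_dots))
    write.csv(ds$rater_dots[[r]], file.path(dir, paste0(r, ".csv")),
              row.names = FALSE)
  sp <- unclass(spec)
  sp$illumination_gain <- as.character(sp$illumination_gain)
  jsonlite::write_json(sp, file.path(dir, "spec.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
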