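#' Rotation-invariant Fourier histogram-of-gradients maps
#'
#' Computes the complex image gradient and, for each angular order
#' m = 0..`hog_max_order` and radial Gaussian scale in `hog_radial_sigmas`,
#' convolves the order-m angular moment of the gradient
#' (|g| exp(i m theta)) with the radial profile and returns the magnitude.
#' Magnitudes of these angular Fourier coefficients are invariant to a
#' global rotation of the local gradient-orientation distribution.
#'
#' @param channel Numeric matrix.
#' @param cfg A [feature_config()].
#' @return Named list of numeric matrices, `fhog_m<m>_s<sigma>`.
#' @export
fourier_hog <- function(channel, cfg = feature_config()) {
  stopifnot(is.matrix(channel), all(is.finite(channel)))
  n <- nrow(channel); m <- ncol(channel)
  clamp <- function(i, k) pmin(pmax(i, 1L), k)
  gy <- (channel[clamp(2:(n + 1), n), , drop = FALSE] -
         channel[clamp(0:(n - 1), n), , drop = FALSE]) / 2
  gx <- (channel[, clamp(2:(m + 1), m), drop = FALSE] -
         channel[, clamp(0:(m - 1), m), drop = FALSE]) / 2
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx)
  out <- list()
  for (ord in 0:cfg$hog_max_order) {
    re <- mag * cos(ord * ang)
    im <- mag * sin(ord * ang)
    for (sg in cfg$hog_radial_sigmas) {
      k <- gaussian_kernel1d(sg)
      cr <- conv2_sep(re, k)
      ci <- conv2_sep(im, k)
      out[[sprintf("fhog_m%d_s%g", ord, sg)]] <- sqrt(cr^2 + ci^2)
    }
  }
  out
}

#' Sliding-window Haralick texture maps
#'
#' Quantizes the image to `haralick_levels` equal-width gray levels over its
#' intensity range, then computes per pixel, on the `haralick_window`
#' neighborhood, the symmetric normalized gray-level co-occurrence matrix
#' averaged over `haralick_offsets`, and returns contrast, correlation,
#' energy (angular second moment), homogeneity and entropy maps.
#'
#' @inheritParams fourier_hog
#' @return Named list of numeric matrices, `haralick_<statistic>`.
#' @export
haralick_maps <- function(channel, cfg = feature_config()) {
  stopifnot(is.matrix(channel), all(is.finite(channel)))
  q <- quantize_levels(channel, cfg$haralick_levels)
  res <- glcm_stat_maps(q, cfg$haralick_levels,
                        (cfg$haralick_window - 1L) %/% 2L,
                        cfg$haralick_offsets)
  names(res) <- paste0("haralick_", names(res))
  res
}

quantize_levels <- function(x, levels) {
  rng <- range(x)
  if (diff(rng) <= 0) return(matrix(0L, nrow(x), ncol(x)))
  q <- floor((x - rng[1]) / diff(rng) * levels)
  q[q >= levels] <- levels - 1L
  matrix(as.integer(q), nrow(x), ncol(x))
}

#' Local intensity entropy map
#'
#' Shannon entropy (bits) of the `entropy_bins`-bin histogram of intensities
#' in the `entropy_window` neighborhood of each pixel, with bins equal-width
#' over the image's intensity range.
#'
#' @inheritParams fourier_hog
#' @return Numeric matrix.
#' @export
local_entropy <- function(channel, cfg = feature_config()) {
  stopifnot(is.matrix(channel), all(is.finite(channel)))
  rng <- range(channel)
  entropy_map_cpp(channel, (cfg$entropy_window - 1L) %/% 2L,
                  cfg$entropy_bins, rng[1], rng[2])
}

#' Steerable ridge filter
#'
#' Second-derivative-of-Gaussian filtering at scale `ridge_sigma`. The
#' steered response in direction theta is available in closed form from the
#' three basis responses (xx, xy, yy); the ridge strength is the magnitude
#' of the most negative eigenvalue of the local 2x2 response matrix
#' (clamped at 0, bright ridges), and the orientation is the along-ridge
#' eigenvector direction in radians (x = columns, y = rows, modulo pi).
#'
#' @inheritParams fourier_hog
#' @return List with matrices `strength`, `orientation`, and the basis
#'   responses `rxx`, `rxy`, `ryy`.
#' @export
ridge_filter <- function(channel, cfg = feature_config()) {
  stopifnot(is.matrix(channel), all(is.finite(channel)))
  sg <- cfg$ridge_sigma
  g0 <- gaussian_deriv1d(sg, 0)
  g1 <- gaussian_deriv1d(sg, 1)
  g2 <- gaussian_deriv1d(sg, 2)
  rxx <- conv2_sep(channel, krow = g0, kcol = g2)  # d2/dx2, x = columns
  ryy <- conv2_sep(channel, krow = g2, kcol = g0)
  rxy <- conv2_sep(channel, krow = g1, kcol = g1)
  disc <- sqrt(((rxx - ryy) / 2)^2 + rxy^2)
  l2 <- (rxx + ryy) / 2 - disc
  strength <- pmax(-l2, 0)
  orientation <- 0.5 * atan2(2 * rxy, rxx - ryy)  # larger-eigenvalue dir
  orientation <- orientation %% pi
  list(strength = strength, orientation = orientation,
       rxx = rxx, rxy = rxy, ryy = ryy)
}

#' Curvilinear membrane-detector saliency map
#'
#' Two-stage membrane detector: steerable ridge filtering
#' ([ridge_filter()]) followed by stick tensor voting at scale
#' `voting_sigma`. Each sufficiently strong ridge pixel casts a decaying,
#' orientation-aligned tensor vote to its neighborhood; the saliency is
#' lambda1 - lambda2 of the accumulated tensor, which is large along
#' curvilinear (membrane-like) structure and small for isotropic blobs.
#'
#' @inheritParams fourier_hog
#' @return Numeric matrix of saliency values.
#' @export
cmd_map <- function(channel, cfg = feature_config()) {
  rf <- ridge_filter(channel, cfg)
  tensor_vote_cpp(rf$strength, rf$orientation, cfg$voting_sigma,
                  cfg$vote_rel_threshold)
}

#' Extracellular component size map
#'
#' Thresholds the corrected structural channel with Otsu's method to get a
#' tissue mask; the complement (extracellular space) is labeled into
#' connected components and every extracellular pixel is assigned the area
#' of its component. Tissue pixels get 0.
#'
#' @param stack A corrected [channel_stack()].
#' @param cfg A [feature_config()].
#' @return Numeric matrix of component areas.
#' @export
ecs_map <- function(stack, cfg = feature_config()) {
  stopifnot(inherits(stack, "channel_stack"))
  if (!stack$corrected) stop("ecs_map expects an illumination-corrected stack")
  s <- stack$structural
  thr <- otsu_threshold(s)
  tissue <- s >= thr
  extra <- !tissue
  out <- matrix(0, nrow(s), ncol(s))
  if (!any(extra)) return(out)
  lab <- cc_label(extra, 8L)
  areas <- tabulate(lab[lab > 0], max(lab))
  idx <- which(lab > 0)
  out[idx] <- areas[lab[idx]]
  out
}

#' Compute all per-pixel feature maps for one image
#'
#' Runs the five feature families. Families i-iv (Fourier HOG, Haralick,
#' local entropy, membrane detector) are computed on the nuclear and
#' structural channels; the extracellular-component-size map derives from
#' the structural channel and is carried in its map set. The marker channel
#' is never featurized.
#'
#' @param stack A corrected [channel_stack()].
#' @param cfg A [feature_config()].
#' @return A list of class `pixel_feature_maps` with `image_id`, `height`,
#'   `width` and `maps` (`$nuclear`, `$structural`: named lists of
#'   matrices).
#' @export
pixel_feature_maps <- function(stack, cfg = feature_config()) {
  stopifnot(inherits(stack, "channel_stack"))
  if (!stack$corrected)
    stop("pixel_feature_maps expects an illumination-corrected stack")
  family <- function(ch) {
    c(fourier_hog(ch, cfg), haralick_maps(ch, cfg),
      list(entropy = local_entropy(ch, cfg), cmd = cmd_map(ch, cfg)))
  }
  maps <- list(nuclear = family(stack$nuclear),
               structural = c(family(stack$structural),
                              list(ecs = ecs_map(stack, cfg))))
  structure(list(image_id = stack$image_id, height = stack$height,
                 width = stack$width, maps = maps),
            class = "pixel_feature_maps")
}

# ring = dilation of the nucleus by a disc of radius r, minus the nucleus,
# clipped to image bounds; returns 0-based (row, col) matrix
ring_pixels <- function(pixels, height, width, radius) {
  r0 <- max(0L, min(pixels[, 1]) - radius)
  r1 <- min(height - 1L, max(pixels[, 1]) + radius)
  c0 <- max(0L, min(pixels[, 2]) - radius)
  c1 <- min(width - 1L, max(pixels[, 2]) + radius)
  ch <- r1 - r0 + 1L
  cw <- c1 - c0 + 1L
  m <- matrix(0L, ch, cw)
  m[cbind(pixels[, 1] - r0 + 1L, pixels[, 2] - c0 + 1L)] <- 1L
  brush <- EBImage::makeBrush(2L * radius + 1L, shape = "disc")
  d <- EBImage::dilate(m, brush)
  sel <- which(d > 0 & m == 0L)
  if (length(sel) == 0) return(cbind(row = integer(), col = integer()))
  cbind(row = (sel - 1L) %% ch + r0, col = (sel - 1L) %/% ch + c0)
}

region_stats <- function(values) {
  if (length(values) == 0) return(c(mean = 0, median = 0, std = 0, mad = 0))
  c(mean = mean(values), median = median(values),
    std = if (length(values) > 1) sd(values) else 0,
    mad = mad(values, constant = 1))
}

#' Summarize feature maps over one nucleus and its surroundings
#'
#' For each channel, each feature map, and each region (the nucleus pixel
#' set and the perinuclear ring of radius `ring_radius`), emits mean,
#' median, sample standard deviation and (unscaled) median absolute
#' deviation of the map values.
#'
#' @param maps A [pixel_feature_maps()] object for the nucleus's image.
#' @param nucleus One nucleus record from [segment_nuclei()].
#' @param cfg A [feature_config()].
#' @return Named numeric vector; names are
#'   `<channel>.<feature>.<region>.<statistic>` in a fixed order determined
#'   by `cfg`.
#' @export
summarize_nucleus <- function(maps, nucleus, cfg = feature_config()) {
  stopifnot(inherits(maps, "pixel_feature_maps"))
  if (!identical(maps$image_id, nucleus$image_id))
    stop("feature maps and nucleus belong to different images")
  px <- nucleus$pixels
  ring <- ring_pixels(px, maps$height, maps$width, cfg$ring_radius)
  if (nrow(ring) == 0)
    warning("empty ring region for nucleus ", nucleus$nucleus_id,
            "; its ring statistics are 0")
  idx_n <- px[, 1] + 1L + px[, 2] * maps$height
  idx_r <- ring[, 1] + 1L + ring[, 2] * maps$height
  out <- numeric(0)
  for (channel in c("nuclear", "structural")) {
    for (feat in names(maps$maps[[channel]])) {
      grid <- maps$maps[[channel]][[feat]]
      for (region in c("nucleus", "ring")) {
        vals <- grid[if (region == "nucleus") idx_n else idx_r]
        st <- region_stats(vals)
        names(st) <- paste(channel, feat, region, names(st), sep = ".")
        out <- c(out, st)
      }
    }
  }
  out
}

#' Per-nucleus feature table for one image
#'
#' Applies [summarize_nucleus()] to every nucleus and returns the raw
#' (unscaled) per-image feature table.
#'
#' @param maps A [pixel_feature_maps()] object.
#' @param nuclei List of nucleus records for the same image.
#' @param cfg A [feature_config()].
#' @return Data frame with `nucleus_id`, `image_id`, then one column per
#'   named feature in a deterministic order.
#' @export
featurize_nuclei <- function(maps, nuclei, cfg = feature_config()) {
  if (length(nuclei) == 0) stop("no nuclei to featurize")
  rows <- lapply(nuclei, function(n) summarize_nucleus(maps, n, cfg))
  feat <- do.call(rbind, rows)
  df <- data.frame(nucleus_id = vapply(nuclei, `[[`, 0L, "nucleus_id"),
                   image_id = vapply(nuclei, `[[`, "", "image_id"))
  cbind(df, as.data.frame(feat))
}

#' Standardize features within each image
#'
#' Scales every feature column to zero mean and unit (sample) variance
#' using that image's nuclei only, so that descriptors are comparable
#' across images. Constant columns map to 0; an image with fewer than two
#' nuclei has all its columns set to 0 with a warning.
#'
#' @param features Data frame from [featurize_nuclei()], possibly spanning
#'   several images (scaling is grouped by `image_id`).
#' @return Data frame of the same shape with standardized feature columns.
#' @export
scale_per_image <- function(features) {
  stopifnot(all(c("nucleus_id", "image_id") %in% names(features)))
  fcols <- setdiff(names(features), c("nucleus_id", "image_id"))
  out <- features
  for (img in unique(features$image_id)) {
    sel <- features$image_id == img
    if (sum(sel) < 2) {
      warning("image ", img, " has fewer than 2 nuclei; features set to 0")
      out[sel, fcols] <- 0
      next
    }
    block <- as.matrix(features[sel, fcols])
    mu <- colMeans(block)
    sdv <- apply(block, 2, sd)
    z <- sweep(block, 2, mu)
    pos <- sdv > 0
    z[, pos] <- sweep(z[, pos, drop = FALSE], 2, sdv[pos], "/")
    z[, !pos] <- 0
    out[sel, fcols] <- z
  }
  out
}
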