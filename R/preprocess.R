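#' Multi-channel image stack
#'
#' Bundles the registered nuclear (DAPI-like), structural (alpha-actin-like)
#' and optional marker (EdU/TUNEL-like) channels of one image as numeric
#' matrices of identical size.
#'
#' @param nuclear,structural Numeric matrices of nonnegative intensities.
#' @param marker Optional numeric matrix, same size, or `NULL`.
#' @param image_id Character identifier of the image.
#' @param corrected Logical; whether illumination correction has been
#'   applied.
#' @return A list of class `channel_stack` with fields `image_id`, `height`,
#'   `width`, `nuclear`, `structural`, `marker` and `corrected`.
#' @export
channel_stack <- function(nuclear, structural, marker = NULL,
                          image_id = "image", corrected = FALSE) {
  stopifnot(is.matrix(nuclear), is.matrix(structural))
  if (!all(dim(nuclear) == dim(structural)))
    stop("nuclear and structural channels have mismatched shape")
  if (!is.null(marker)) {
    stopifnot(is.matrix(marker))
    if (!all(dim(marker) == dim(nuclear)))
      stop("marker channel has mismatched shape")
  }
  if (min(nuclear) < 0 || min(structural) < 0 ||
      (!is.null(marker) && min(marker) < 0))
    stop("channel intensities must be nonnegative")
  structure(list(image_id = as.character(image_id),
                 height = nrow(nuclear), width = ncol(nuclear),
                 nuclear = nuclear, structural = structural, marker = marker,
                 corrected = isTRUE(corrected)),
            class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  cat(sprintf("<channel_stack> %s: %dx%d, marker %s, corrected=%s\n",
              x$image_id, x$height, x$width,
              if (is.null(x$marker)) "absent" else "present", x$corrected))
  invisible(x)
}

#' Read a multi-channel image
#'
#' Reads a TIFF or PNG image and maps its channels onto the nuclear,
#' structural and (optionally) marker roles. Intensities are kept as read
#' (floating point in \[0, 1\] for standard files).
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @param channel_map Named integer vector assigning channel indices to
#'   roles, e.g. `c(nuclear = 3, structural = 1, marker = 2)` for RGB with
#'   blue nuclei and red structure. `nuclear` and `structural` are
#'   mandatory; omit `marker` if absent.
#' @param image_id Image identifier; defaults to the file name without
#'   extension.
#' @return A [channel_stack()] with `corrected = FALSE`.
#' @export
read_image <- function(path,
                       channel_map = c(nuclear = 3, structural = 1,
                                       marker = 2),
                       image_id = NULL) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
                tif = ,
                tiff = tiff::readTIFF(path),
                png = png::readPNG(path),
                stop("unsupported image format: .", ext))
  if (is.matrix(arr)) arr <- array(arr, c(dim(arr), 1L))
  nchan <- dim(arr)[3]
  roles <- c("nuclear", "structural")
  if (!all(roles %in% names(channel_map)))
    stop("channel_map must name 'nuclear' and 'structural' roles")
  for (role in intersect(c(roles, "marker"), names(channel_map))) {
    idx <- channel_map[[role]]
    if (idx < 1 || idx > nchan)
      stop(sprintf("channel index %d for role '%s' out of range (%d channels)",
                   idx, role, nchan))
  }
  if (is.null(image_id))
    image_id <- tools::file_path_sans_ext(basename(path))
  grab <- function(role) {
    if (!role %in% names(channel_map)) return(NULL)
    matrix(as.numeric(arr[, , channel_map[[role]]]), dim(arr)[1], dim(arr)[2])
  }
  channel_stack(nuclear = grab("nuclear"), structural = grab("structural"),
                marker = grab("marker"), image_id = image_id,
                corrected = FALSE)
}

#' Correct illumination inhomogeneity
#'
#' Estimates the local background as a Gaussian blur (scale
#' `background_sigma`, reflective boundary) of the structural channel and
#' divides every channel by it pixelwise. The divisor is floored at
#' `background_floor_epsilon * max(background)`; pixels whose background
#' falls at or below the floor are set to 0 (dead regions).
#'
#' @param stack An uncorrected [channel_stack()].
#' @param cfg A [preprocess_config()].
#' @return The corrected stack (`corrected = TRUE`).
#' @export
correct_illumination <- function(stack, cfg = preprocess_config()) {
  stopifnot(inherits(stack, "channel_stack"))
  if (stack$corrected) stop("stack is already illumination-corrected")
  if (max(stack$structural) <= 0)
    stop("structural channel is identically zero; no background estimable")
  bg <- gaussian_blur(stack$structural, cfg$background_sigma)
  floorv <- cfg$background_floor_epsilon * max(bg)
  dead <- bg <= floorv
  denom <- pmax(bg, floorv)
  divide <- function(ch) {
    if (is.null(ch)) return(NULL)
    out <- ch / denom
    out[dead] <- 0
    out
  }
  channel_stack(nuclear = divide(stack$nuclear),
                structural = divide(stack$structural),
                marker = divide(stack$marker),
                image_id = stack$image_id, corrected = TRUE)
}

otsu_threshold <- function(x) {
  rng <- range(x)
  if (diff(rng) <= 0) return(rng[1])
  EBImage::otsu(x, range = rng, levels = 256L)
}

#' Segment candidate nuclei
#'
#' Binarizes the corrected nuclear channel by Otsu's threshold, labels
#' connected components at the configured connectivity, and discards
#' components with area below `min_nucleus_area`. Records are sorted by
#' centroid (row, then column) and renumbered consecutively from 1.
#'
#' @param stack A corrected [channel_stack()].
#' @param cfg A [preprocess_config()].
#' @return A list of nucleus records, each a list with `nucleus_id`,
#'   `image_id`, `pixels` (two-column matrix of 0-based (row, col)
#'   coordinates), `area` and `centroid` (0-based (row, col)).
#' @export
segment_nuclei <- function(stack, cfg = preprocess_config()) {
  stopifnot(inherits(stack, "channel_stack"))
  if (!stack$corrected)
    stop("segment_nuclei expects an illumination-corrected stack")
  nuc <- stack$nuclear
  if (diff(range(nuc)) <= 0) return(list())
  thr <- otsu_threshold(nuc)
  mask <- nuc > thr
  lab <- cc_label(mask, cfg$connectivity)
  nlab <- max(lab)
  if (nlab == 0) return(list())
  idx <- which(lab > 0)
  comp <- lab[idx]
  rows <- (idx - 1L) %% nrow(nuc)       # 0-based
  cols <- (idx - 1L) %/% nrow(nuc)
  areas <- tabulate(comp, nlab)
  keep <- which(areas >= cfg$min_nucleus_area)
  if (length(keep) == 0) return(list())
  recs <- lapply(keep, function(k) {
    sel <- comp == k
    px <- cbind(row = rows[sel], col = cols[sel])
    list(nucleus_id = NA_integer_, image_id = stack$image_id, pixels = px,
         area = nrow(px), centroid = c(row = mean(px[, 1]),
                                       col = mean(px[, 2])))
  })
  ord <- order(vapply(recs, function(r) r$centroid[1], 0),
               vapply(recs, function(r) r$centroid[2], 0))
  recs <- recs[ord]
  for (i in seq_along(recs)) recs[[i]]$nucleus_id <- i
  recs
}

#' Tabulate nucleus records
#'
#' @param nuclei A list of nucleus records from [segment_nuclei()].
#' @return A data frame with columns `nucleus_id`, `image_id`, `row`, `col`
#'   (centroid, 0-based) and `area`.
#' @export
nuclei_table <- function(nuclei) {
  if (length(nuclei) == 0) {
    return(data.frame(nucleus_id = integer(), image_id = character(),
                      row = numeric(), col = numeric(), area = integer()))
  }
  data.frame(
    nucleus_id = vapply(nuclei, `[[`, 0L, "nucleus_id"),
    image_id = vapply(nuclei, `[[`, "", "image_id"),
    row = vapply(nuclei, function(n) unname(n$centroid[1]), 0),
    col = vapply(nuclei, function(n) unname(n$centroid[2]), 0),
    area = vapply(nuclei, `[[`, 0L, "area"))
}

#' Write the nuclei table to CSV
#'
#' Centroids are written to 3 decimal places.
#'
#' @param nuclei A list of nucleus records.
#' @param path Output CSV path.
#' @export
write_nuclei_csv <- function(nuclei, path) {
  tab <- nuclei_table(nuclei)
  tab$row <- round(tab$row, 3)
  tab$col <- round(tab$col, 3)
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
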