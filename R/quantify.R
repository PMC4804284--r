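#' Call marker positivity per nucleus
#'
#' Binarizes the corrected marker channel with Otsu's threshold; a nucleus
#' is marker-positive iff the fraction of its pixels above the threshold is
#' at least `min_fraction`. The fraction rule is robust to marker signal
#' covering only part of the nucleus.
#'
#' @param stack A corrected [channel_stack()] with a marker channel.
#' @param nuclei List of nucleus records from [segment_nuclei()].
#' @param min_fraction Minimum fraction of above-threshold nucleus pixels.
#' @return Logical vector, one element per nucleus.
#' @export
marker_positive <- function(stack, nuclei, min_fraction = 0.25) {
  stopifnot(inherits(stack, "channel_stack"))
  if (is.null(stack$marker)) stop("stack has no marker channel")
  if (!stack$corrected)
    stop("marker_positive expects an illumination-corrected stack")
  mk <- stack$marker
  thr <- otsu_threshold(mk)
  vapply(nuclei, function(n) {
    vals <- mk[n$pixels[, 1] + 1L + n$pixels[, 2] * nrow(mk)]
    mean(vals > thr) >= min_fraction
  }, logical(1))
}

#' Build prediction records from model scores
#'
#' @param nuclei Data frame from [nuclei_table()] (or list of records).
#' @param scores Numeric scores aligned with `nuclei`.
#' @param threshold Probability threshold; `predicted = "target"` iff
#'   `score >= threshold`.
#' @return Data frame with `nucleus_id`, `image_id`, `row`, `col`, `score`,
#'   `predicted`, `user_decision` (initialized to `"untouched"`).
#' @export
prediction_records <- function(nuclei, scores, threshold) {
  if (is.list(nuclei) && !is.data.frame(nuclei)) nuclei <- nuclei_table(nuclei)
  stopifnot(nrow(nuclei) == length(scores))
  data.frame(nucleus_id = nuclei$nucleus_id, image_id = nuclei$image_id,
             row = nuclei$row, col = nuclei$col, score = scores,
             predicted = ifelse(scores >= threshold, "target", "non_target"),
             user_decision = "untouched")
}

#' Apply file-based user corrections to predictions
#'
#' The optional correction step lets a user rule out false positives (or
#' restore false negatives) after reviewing predictions: `accept` forces
#' `target`, `reject` forces `non_target`, nuclei absent from the
#' corrections are untouched. The operation is idempotent and independent
#' of the row order of the corrections. Marker channels play no role here;
#' quantification stains are masked from the correction decision.
#'
#' @param predictions Data frame from [prediction_records()].
#' @param corrections Data frame with `image_id`, `nucleus_id`, `decision`
#'   (`accept`/`reject`), or a path to such a CSV.
#' @return The predictions with `predicted` and `user_decision` updated.
#' @export
apply_corrections <- function(predictions, corrections) {
  if (is.character(corrections))
    corrections <- read.csv(corrections, stringsAsFactors = FALSE)
  if (nrow(corrections) == 0) return(predictions)
  stopifnot(all(c("image_id", "nucleus_id", "decision") %in%
                names(corrections)))
  bad <- setdiff(unique(corrections$decision), c("accept", "reject"))
  if (length(bad)) stop("unknown decisions: ", paste(bad, collapse = ", "))
  pkey <- paste(predictions$image_id, predictions$nucleus_id)
  ckey <- paste(corrections$image_id, corrections$nucleus_id)
  missing <- !(ckey %in% pkey)
  if (any(missing))
    stop("corrections reference unknown nuclei: ",
         paste(unique(ckey[missing]), collapse = "; "))
  dup <- duplicated(ckey)
  if (any(dup))
    stop("conflicting corrections for: ",
         paste(unique(ckey[dup]), collapse = "; "))
  i <- match(ckey, pkey)
  predictions$user_decision[i] <- corrections$decision
  predictions$predicted[i] <- ifelse(corrections$decision == "accept",
                                     "target", "non_target")
  predictions
}

pct <- function(num, den) if (den > 0) 100 * num / den else if (num == 0) 0 else NA_real_

#' Quantify target and marker-positive nuclei
#'
#' Counts, per image and pooled over summed counts, the total nuclei,
#' target (cell-of-interest) nuclei, marker-positive nuclei and
#' marker-positive target nuclei, with the four derived percentages:
#' targets among all nuclei, marker-positives among all nuclei,
#' marker-positive targets among targets, and marker-positive targets
#' among marker-positives.
#'
#' @param nuclei Data frame from [nuclei_table()] (or list of records).
#' @param target_flags Logical vector (post-correction target calls).
#' @param marker_flags Logical vector from [marker_positive()], or `NULL`
#'   when no marker channel exists (marker counts are then 0).
#' @return Data frame of class `nq_quant_report`, one row per image plus a
#'   `"pooled"` row; percentages are `NA` for an image with zero nuclei.
#' @export
quantify_nuclei <- function(nuclei, target_flags, marker_flags = NULL) {
  if (is.list(nuclei) && !is.data.frame(nuclei)) nuclei <- nuclei_table(nuclei)
  n <- nrow(nuclei)
  if (is.null(marker_flags)) marker_flags <- rep(FALSE, n)
  stopifnot(length(target_flags) == n, length(marker_flags) == n)
  one <- function(t, m) {
    counts <- c(n_total_nuclei = length(t), n_target = sum(t),
                n_marker_pos = sum(m), n_marker_pos_target = sum(t & m))
    if (counts[1] == 0) {
      # no nuclei at all: percentages are not available
      p <- rep(NA_real_, 4)
    } else {
      p <- c(pct(counts[2], counts[1]), pct(counts[3], counts[1]),
             pct(counts[4], counts[2]), pct(counts[4], counts[3]))
    }
    data.frame(t(counts),
               pct_target_of_total = p[1], pct_marker_of_total = p[2],
               pct_marker_target_of_target = p[3],
               pct_marker_target_of_marker = p[4])
  }
  imgs <- unique(nuclei$image_id)
  rows <- lapply(imgs, function(img) {
    sel <- nuclei$image_id == img
    cbind(image_id = img, one(target_flags[sel], marker_flags[sel]))
  })
  rows[[length(rows) + 1]] <- cbind(image_id = "pooled",
                                    one(target_flags, marker_flags))
  rep <- do.call(rbind, rows)
  rownames(rep) <- NULL
  class(rep) <- c("nq_quant_report", class(rep))
  rep
}

#' Write a quantification report
#'
#' Writes both CSV and JSON forms; before writing, verifies that every
#' percentage recomputes exactly from the integer counts in the same row.
#'
#' @param report An `nq_quant_report` from [quantify_nuclei()].
#' @param path Output path without extension (writes `<path>.csv` and
#'   `<path>.json`), or a path ending in `.csv`/`.json` for one format.
#' @export
write_quant_report <- function(report, path) {
  stopifnot(inherits(report, "nq_quant_report"))
  for (i in seq_len(nrow(report))) {
    r <- report[i, ]
    chk <- c(pct(r$n_target, r$n_total_nuclei),
             pct(r$n_marker_pos, r$n_total_nuclei),
             pct(r$n_marker_pos_target, r$n_target),
             pct(r$n_marker_pos_target, r$n_marker_pos))
    got <- c(r$pct_target_of_total, r$pct_marker_of_total,
             r$pct_marker_target_of_target, r$pct_marker_target_of_marker)
    if (!isTRUE(all.equal(chk, got, tolerance = 1e-12)))
      stop("report self-consistency check failed for image ", r$image_id)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    write.csv(report, path, row.names = FALSE)
  } else if (ext == "json") {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  } else {
    write.csv(report, paste0(path, ".csv"), row.names = FALSE)
    jsonlite::write_json(report, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
  }
  invisible(path)
}
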