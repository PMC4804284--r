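#' Build a multi-rater selection matrix over nuclei
#'
#' Matches each rater's annotation dots to the segmented nuclei
#' ([match_annotations()], same radius rule) and tabulates, per nucleus,
#' how many raters selected it. Multiple dots by one rater within radius
#' of the same nucleus count once: selection is binary per rater.
#'
#' @param nuclei Data frame from [nuclei_table()] (or list of records).
#' @param rater_dots Named list, one element per rater, each a data frame
#'   of dot coordinates (`row`, `col`) for the same image set.
#' @param radius Matching radius in pixels (default 15).
#' @return A list of class `nq_rater_matrix` with `items` (data frame
#'   `image_id`, `nucleus_id`), `raters`, and `counts` (items x 2 integer
#'   matrix, columns `selected`, `not_selected`).
#' @export
build_rater_matrix <- function(nuclei, rater_dots, radius = 15) {
  if (is.list(nuclei) && !is.data.frame(nuclei)) nuclei <- nuclei_table(nuclei)
  stopifnot(length(rater_dots) >= 2)
  k <- length(rater_dots)
  one_rater <- function(dots) {
    dots <- as.data.frame(dots)
    if (!"image_id" %in% names(dots)) {
      return(match_annotations(nuclei, dots, radius)$label == "target")
    }
    # dots carry image ids: match within each image separately
    bad <- setdiff(unique(dots$image_id), unique(nuclei$image_id))
    if (length(bad))
      stop("rater annotations reference unknown images: ",
           paste(bad, collapse = ", "))
    sel <- logical(nrow(nuclei))
    for (img in unique(nuclei$image_id)) {
      ni <- nuclei$image_id == img
      di <- dots[dots$image_id == img, c("row", "col"), drop = FALSE]
      sel[ni] <- match_annotations(nuclei[ni, ], di, radius)$label ==
        "target"
    }
    sel
  }
  sel <- matrix(vapply(rater_dots, one_rater, logical(nrow(nuclei))),
                nrow = nrow(nuclei))
  counts <- cbind(selected = rowSums(sel), not_selected = k - rowSums(sel))
  structure(list(items = nuclei[, c("image_id", "nucleus_id")],
                 raters = names(rater_dots) %||% paste0("rater", seq_len(k)),
                 counts = counts),
            class = "nq_rater_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fleiss kappa with large-sample standard error
#'
#' Chance-corrected agreement of k raters assigning n items to two
#' categories (selected / not selected): kappa = (Pbar - Pe) / (1 - Pe),
#' where Pbar is the mean per-item observed agreement and Pe the chance
#' agreement from pooled category proportions. The standard error uses the
#' Fleiss-Nee-Landis large-sample variance for overall kappa.
#'
#' @param matrix An `nq_rater_matrix` from [build_rater_matrix()], or a
#'   plain items x categories count matrix with constant row sum k >= 2.
#' @return A list of class `nq_agreement` with `kappa`, `se`, `n_items`,
#'   `n_raters`, `p_bar`, `p_e` and `band` (see [interpret_kappa()]).
#' @export
fleiss_kappa <- function(matrix) {
  counts <- if (inherits(matrix, "nq_rater_matrix")) matrix$counts else
    as.matrix(matrix)
  n <- nrow(counts)
  ks <- unique(rowSums(counts))
  if (length(ks) != 1) stop("all items must be rated by the same number of raters")
  k <- ks
  if (k < 2) stop("need at least 2 raters")
  pj <- colSums(counts) / (n * k)
  pe <- sum(pj^2)
  if (pe >= 1)
    stop("all raters placed all items in one category; kappa is undefined")
  pi_ <- (rowSums(counts^2) - k) / (k * (k - 1))
  pbar <- mean(pi_)
  kappa <- (pbar - pe) / (1 - pe)
  qj <- pj * (1 - pj)
  se <- sqrt(2 / (n * k * (k - 1))) *
    sqrt(sum(qj)^2 - sum(qj * (1 - 2 * pj))) / sum(qj)
  structure(list(kappa = kappa, se = se, n_items = n, n_raters = k,
                 p_bar = pbar, p_e = pe, band = interpret_kappa(kappa)),
            class = "nq_agreement")
}

#' @export
print.nq_agreement <- function(x, ...) {
  cat(sprintf("Fleiss kappa %.3f (se %.4f), %d items, %d raters: %s agreement\n",
              x$kappa, x$se, x$n_items, x$n_raters, x$band))
  invisible(x)
}

#' Interpret a kappa value on the standard agreement bands
#'
#' Bands: 0.01-0.20 slight, 0.21-0.40 fair, 0.41-0.60 moderate, 0.61-0.80
#' substantial, above 0.80 almost perfect; values at or below 0 are "poor".
#' The cutpoints are printed at 2 decimals, so the input is rounded
#' half-up to 2 decimals before banding (values in a printed gap such as
#' 0.205 land on the nearer band edge).
#'
#' @param kappa Finite kappa value.
#' @return One of `"poor"`, `"slight"`, `"fair"`, `"moderate"`,
#'   `"substantial"`, `"almost_perfect"`.
#' @export
interpret_kappa <- function(kappa) {
  stopifnot(is.finite(kappa))
  r <- floor(kappa * 100 + 0.5 + 1e-9) / 100  # round half-up, 2 decimals
  if (r <= 0) "poor"
  else if (r <= 0.20) "slight"
  else if (r <= 0.40) "fair"
  else if (r <= 0.60) "moderate"
  else if (r <= 0.80) "substantial"
  else "almost_perfect"
}

#' Two-sided z-test comparing two independent kappas
#'
#' z = (kappa_a - kappa_b) / sqrt(se_a^2 + se_b^2), with a two-sided normal
#' p-value; the standard test for a difference of agreement between
#' independent samples.
#'
#' @param a,b `nq_agreement` objects (or lists with `kappa` and `se`).
#' @return List with `z` and `p`.
#' @export
kappa_z_test <- function(a, b) {
  v <- a$se^2 + b$se^2
  if (!is.finite(v) || v <= 0) stop("nonpositive pooled variance")
  z <- (a$kappa - b$kappa) / sqrt(v)
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Write an agreement result as JSON
#'
#' @param result An `nq_agreement`.
#' @param path Output path.
#' @export
write_agreement_json <- function(result, path) {
  stopifnot(inherits(result, "nq_agreement"))
  jsonlite::write_json(unclass(result)[c("kappa", "se", "n_items",
                                         "n_raters", "band")],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_agreement_json
#' @export
read_agreement_json <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "nq_agreement")
}
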