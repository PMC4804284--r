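#' Match annotation dots to nuclei
#'
#' A nucleus is labeled `target` iff some annotation dot lies within
#' `radius` pixels (Euclidean) of its centroid. Each dot is additionally
#' assigned to its nearest in-radius centroid (ties broken by smaller
#' `nucleus_id`) for provenance; dots with no centroid in radius are
#' reported as unmatched.
#'
#' @param nuclei Data frame with `nucleus_id`, `image_id`, `row`, `col`
#'   (centroids; see [nuclei_table()]), or a list of nucleus records.
#' @param dots Data frame (or two-column matrix) of dot coordinates `row`,
#'   `col` in the same 0-based frame.
#' @param radius Matching radius in pixels. Default 15, roughly the largest
#'   target-nucleus radius at the working magnification.
#' @return Data frame with `image_id`, `nucleus_id`, `label`
#'   (`"target"`/`"non_target"`) and `dot_id` (provenance, `NA` if none
#'   assigned); attribute `unmatched_dots` holds indices of unassigned
#'   dots.
#' @export
match_annotations <- function(nuclei, dots, radius = 15) {
  if (is.list(nuclei) && !is.data.frame(nuclei)) nuclei <- nuclei_table(nuclei)
  dots <- as.data.frame(dots)
  if (!all(c("row", "col") %in% names(dots)) && ncol(dots) >= 2)
    names(dots)[1:2] <- c("row", "col")
  n <- nrow(nuclei)
  labels <- rep("non_target", n)
  dot_id <- rep(NA_integer_, n)
  unmatched <- integer(0)
  if (nrow(dots) > 0 && n > 0) {
    d2 <- outer(dots$row, nuclei$row, "-")^2 + outer(dots$col, nuclei$col, "-")^2
    inrad <- d2 <= radius^2
    labels[colSums(inrad) > 0] <- "target"
    for (i in seq_len(nrow(dots))) {
      cand <- which(inrad[i, ])
      if (length(cand) == 0) {
        unmatched <- c(unmatched, i)
        next
      }
      best <- cand[order(d2[i, cand], nuclei$nucleus_id[cand])][1]
      if (is.na(dot_id[best])) dot_id[best] <- i
    }
  } else if (nrow(dots) > 0) {
    unmatched <- seq_len(nrow(dots))
  }
  out <- data.frame(image_id = nuclei$image_id,
                    nucleus_id = nuclei$nucleus_id,
                    label = labels, dot_id = dot_id)
  attr(out, "unmatched_dots") <- unmatched
  out
}

#' Train an L2-regularized logistic regression nucleus classifier
#'
#' Fits the liblinear-style objective (logistic loss with ridge penalty,
#' cost parameter `C`) on standardized feature vectors; the fit is
#' deterministic given the data and `C`. Scores are posterior probabilities
#' through the logistic link.
#'
#' @param x Numeric matrix (nuclei x features) of standardized descriptors,
#'   with column names.
#' @param y Labels: logical, 0/1, or `"target"`/`"non_target"`.
#' @param C Positive cost parameter (inverse regularization strength).
#' @param class_weight `"none"` or `"balanced"` (inverse-frequency
#'   observation weights).
#' @param threshold Initial probability threshold stored in the model.
#' @param training_image_ids Character vector recorded for provenance.
#' @return A list of class `nq_model` with `weights`, `intercept`,
#'   `feature_names`, `regularization_C`, `threshold` and
#'   `training_image_ids`.
#' @export
train_logreg <- function(x, y, C = 1.0, class_weight = c("none", "balanced"),
                         threshold = 0.5, training_image_ids = character()) {
  class_weight <- match.arg(class_weight)
  x <- as.matrix(x)
  ybin <- as_binary_label(y)
  if (length(unique(ybin)) < 2)
    stop("training set contains a single class; need both target and non_target")
  stopifnot(C > 0, nrow(x) == length(ybin))
  n <- nrow(x)
  w <- rep(1, n)
  if (class_weight == "balanced") {
    tab <- table(ybin)
    w <- n / (2 * as.numeric(tab[as.character(ybin)]))
  }
  lambda <- 1 / (n * C)
  xfit <- x
  if (ncol(xfit) == 1) {
    # glmnet requires >= 2 columns; pad with an all-zero dummy
    xfit <- cbind(xfit, `.dummy` = 0)
  }
  # short warm-start path ending at the requested lambda keeps glmnet stable
  fit <- glmnet::glmnet(xfit, ybin, family = "binomial", alpha = 0,
                        lambda = c(lambda * 100, lambda * 10, lambda),
                        weights = w, standardize = FALSE, thresh = 1e-12,
                        maxit = 1e6)
  cf <- as.numeric(stats::coef(fit, s = lambda))[seq_len(ncol(x) + 1)]
  structure(list(weights = cf[-1], intercept = cf[1],
                 feature_names = colnames(x), regularization_C = C,
                 threshold = threshold,
                 training_image_ids = unique(as.character(training_image_ids))),
            class = "nq_model")
}

as_binary_label <- function(y) {
  if (is.character(y) || is.factor(y)) {
    y <- as.character(y)
    bad <- setdiff(unique(y), c("target", "non_target"))
    if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "))
    as.integer(y == "target")
  } else {
    as.integer(as.logical(y))
  }
}

#' Score nuclei with a trained model
#'
#' @param model An `nq_model` from [train_logreg()].
#' @param x Feature matrix with columns matching `model$feature_names`.
#' @return Numeric vector of posterior probabilities of `target`.
#' @export
predict_scores <- function(model, x) {
  stopifnot(inherits(model, "nq_model"))
  x <- as.matrix(x)
  if (!is.null(colnames(x))) {
    if (!all(model$feature_names %in% colnames(x)))
      stop("feature matrix is missing model features")
    x <- x[, model$feature_names, drop = FALSE]
  } else if (ncol(x) != length(model$weights)) {
    stop("feature matrix width does not match model")
  }
  as.numeric(plogis(x %*% model$weights + model$intercept))
}

#' Leave-image-out cross-validated scores
#'
#' For each image, trains a model on all other images' nuclei and scores
#' that image's nuclei, so no nucleus is ever scored by a model that saw
#' its own image.
#'
#' @param features Standardized feature data frame spanning >= 2 images
#'   (`nucleus_id`, `image_id`, feature columns).
#' @param labels Data frame from [match_annotations()] (or with `image_id`,
#'   `nucleus_id`, `label`), aligned by (`image_id`, `nucleus_id`).
#' @param C,class_weight Passed to [train_logreg()].
#' @return Data frame `image_id`, `nucleus_id`, `label`, `score`; attribute
#'   `fold_models` is a named list of the per-fold `nq_model`s.
#' @export
loio_cv <- function(features, labels, C = 1.0,
                    class_weight = c("none", "balanced")) {
  class_weight <- match.arg(class_weight)
  images <- unique(features$image_id)
  if (length(images) < 2) stop("leave-image-out needs at least 2 images")
  key <- function(df) paste(df$image_id, df$nucleus_id)
  lab <- labels$label[match(key(features), key(labels))]
  if (anyNA(lab)) stop("labels missing for some nuclei")
  fcols <- setdiff(names(features), c("nucleus_id", "image_id"))
  x <- as.matrix(features[, fcols])
  out <- data.frame(image_id = features$image_id,
                    nucleus_id = features$nucleus_id,
                    label = lab, score = NA_real_)
  models <- list()
  for (img in images) {
    test <- features$image_id == img
    ytr <- lab[!test]
    if (length(unique(ytr)) < 2)
      stop("training complement of image ", img, " is single-class")
    m <- train_logreg(x[!test, , drop = FALSE], ytr, C = C,
                      class_weight = class_weight,
                      training_image_ids = setdiff(images, img))
    out$score[test] <- predict_scores(m, x[test, , drop = FALSE])
    models[[img]] <- m
  }
  attr(out, "fold_models") <- models
  out
}

#' Precision/recall curve over score thresholds
#'
#' One curve point per distinct score value, predicting `target` where
#' `score >= threshold`; TP/FP/FN are exact integer counts and
#' precision = TP/(TP+FP), recall = TP/(TP+FN) hold exactly at every point.
#'
#' @param scores Numeric score vector.
#' @param labels Labels aligned with `scores` (any form accepted by
#'   [train_logreg()]).
#' @return Data frame of class `nq_pr_curve` with `threshold` (descending),
#'   `tp`, `fp`, `fn`, `precision`, `recall`.
#' @export
pr_curve <- function(scores, labels) {
  y <- as_binary_label(labels)
  stopifnot(length(scores) == length(y))
  npos <- sum(y)
  if (npos == 0) stop("no target nuclei; recall is undefined")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  yo <- y[ord]
  ctp <- cumsum(yo)
  cfp <- cumsum(1 - yo)
  last <- !duplicated(s, fromLast = TRUE)  # last index of each distinct score
  tp <- ctp[last]
  fp <- cfp[last]
  out <- data.frame(threshold = s[last], tp = tp, fp = fp, fn = npos - tp,
                    precision = ifelse(tp + fp > 0, tp / (tp + fp), 1),
                    recall = tp / npos)
  class(out) <- c("nq_pr_curve", class(out))
  out
}

#' Select an operating threshold from a precision/recall curve
#'
#' Returns the largest threshold whose recall meets the floor
#' `target_recall`, i.e. the most precise operating point subject to the
#' recall constraint; both quoted operating regimes of the method are
#' recall-first.
#'
#' @param curve An `nq_pr_curve` from [pr_curve()].
#' @param target_recall Required minimum recall in (0, 1].
#' @return List with `threshold`, `precision`, `recall` at the selected
#'   point.
#' @export
select_threshold <- function(curve, target_recall) {
  stopifnot(inherits(curve, "nq_pr_curve"), nrow(curve) > 0,
            target_recall > 0, target_recall <= 1)
  ok <- which(curve$recall >= target_recall)
  if (length(ok) == 0)
    stop(sprintf("target recall %.3f exceeds maximum achievable %.3f",
                 target_recall, max(curve$recall)))
  i <- ok[which.max(curve$threshold[ok])]
  list(threshold = curve$threshold[i], precision = curve$precision[i],
       recall = curve$recall[i])
}

#' Write / read a trained model as JSON
#'
#' @param model An `nq_model`.
#' @param path Output path.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "nq_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(m[c("weights", "intercept", "feature_names", "regularization_C",
                "threshold", "training_image_ids")], class = "nq_model")
}
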