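nuclei_df <- function(rows, cols, image_id = "a") {
  data.frame(nucleus_id = seq_along(rows), image_id = image_id,
             row = rows, col = cols, area = 10L)
}

test_that("annotation dots label nuclei inside the 15-pixel radius only", {
  nd <- nuclei_df(c(50, 120), c(50, 120))
  lab14 <- match_annotations(nd, data.frame(row = 50, col = 64), radius = 15)
  expect_equal(lab14$label, c("target", "non_target"))
  lab16 <- match_annotations(nd, data.frame(row = 50, col = 66), radius = 15)
  expect_equal(lab16$label, c("non_target", "non_target"))
  expect_equal(attr(lab16, "unmatched_dots"), 1L)

  # no dots: everything non_target
  lab0 <- match_annotations(nd, data.frame(row = numeric(), col = numeric()))
  expect_true(all(lab0$label == "non_target"))
})

test_that("dots are assigned to the nearest in-radius centroid with id
           tie-breaks, matching an exhaustive oracle", {
  nd <- nuclei_df(c(10, 10), c(20, 42))
  # dot at distance 10 from nucleus 1 and 12 from nucleus 2
  lab <- match_annotations(nd, data.frame(row = 10, col = 30), radius = 15)
  expect_equal(lab$dot_id, c(1L, NA_integer_))
  expect_equal(lab$label, c("target", "target"))  # both within radius

  set.seed(19)
  for (i in 1:20) {
    nd2 <- nuclei_df(runif(8, 0, 100), runif(8, 0, 100))
    dots <- data.frame(row = runif(5, 0, 100), col = runif(5, 0, 100))
    lab2 <- match_annotations(nd2, dots, radius = 20)
    # oracle: exhaustive per-dot nearest neighbor within radius
    for (d in seq_len(nrow(dots))) {
      dist <- sqrt((nd2$row - dots$row[d])^2 + (nd2$col - dots$col[d])^2)
      if (min(dist) > 20) {
        expect_true(d %in% attr(lab2, "unmatched_dots"))
      }
    }
    # label oracle: in-radius existence
    for (k in seq_len(nrow(nd2))) {
      dist <- sqrt((dots$row - nd2$row[k])^2 + (dots$col - nd2$col[k])^2)
      expect_equal(lab2$label[k] == "target", any(dist <= 20))
    }
  }
})

test_that("logistic training separates a separable problem and is
           deterministic", {
  set.seed(4)
  n <- 100
  x <- matrix(c(rnorm(n, 1, 0.1), rnorm(n, -1, 0.1)), ncol = 1)
  colnames(x) <- "f1"
  y <- rep(c("target", "non_target"), each = n)
  m <- train_logreg(x, y)
  xt <- matrix(c(rnorm(20, 1, 0.1), rnorm(20, -1, 0.1)), ncol = 1,
               dimnames = list(NULL, "f1"))
  s <- predict_scores(m, xt)
  expect_gt(min(s[1:20]), max(s[21:40]))
  expect_gt(m$weights[1], 0)  # positively associated feature

  # decision boundary: zero logit gives probability one half
  x0 <- matrix(-m$intercept / m$weights[1], 1, 1,
               dimnames = list(NULL, "f1"))
  expect_equal(predict_scores(m, x0), 0.5, tolerance = 1e-9)

  m2 <- train_logreg(x, y)
  expect_identical(m$weights, m2$weights)
  expect_identical(m$intercept, m2$intercept)

  expect_error(train_logreg(x, rep("target", 2 * n)), "single class")
})

test_that("model JSON round-trips", {
  set.seed(8)
  x <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("a", "b")))
  y <- as.integer(x[, 1] + rnorm(30, 0, 0.4) > 0)
  m <- train_logreg(x, y, C = 2, training_image_ids = c("i1", "i2"))
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, path)
  m2 <- read_model_json(path)
  expect_equal(m2$weights, m$weights)
  expect_equal(m2$intercept, m$intercept)
  expect_equal(m2$feature_names, m$feature_names)
  expect_equal(predict_scores(m2, x), predict_scores(m, x))
})

make_loio_data <- function(n_images = 3, n_per = 30, seed = 1, sep = 2) {
  set.seed(seed)
  out <- lapply(seq_len(n_images), function(i) {
    y <- rep(c(1, 0), length.out = n_per)
    data.frame(nucleus_id = seq_len(n_per),
               image_id = sprintf("img%d", i),
               f1 = rnorm(n_per, ifelse(y == 1, sep / 2, -sep / 2), 1),
               f2 = rnorm(n_per), label = ifelse(y == 1, "target",
                                                 "non_target"))
  })
  do.call(rbind, out)
}

test_that("leave-image-out scoring never trains on the scored image", {
  d <- make_loio_data(3)
  res <- loio_cv(d[, 1:4], d[, c("image_id", "nucleus_id", "label")])
  models <- attr(res, "fold_models")
  expect_length(models, 3)
  for (img in names(models)) {
    expect_false(img %in% models[[img]]$training_image_ids)
    expect_setequal(models[[img]]$training_image_ids,
                    setdiff(unique(d$image_id), img))
  }
  expect_false(anyNA(res$score))
})

test_that("two identical images give mirrored leave-image-out scores", {
  d1 <- make_loio_data(1, seed = 5)
  d2 <- d1
  d2$image_id <- "img2"
  d <- rbind(d1, d2)
  res <- loio_cv(d[, 1:4], d[, c("image_id", "nucleus_id", "label")])
  expect_equal(res$score[res$image_id == "img1"],
               res$score[res$image_id == "img2"], tolerance = 1e-9)
})

test_that("pooled leave-image-out scores are invariant to image order", {
  d <- make_loio_data(4, seed = 9)
  res1 <- loio_cv(d[, 1:4], d[, c("image_id", "nucleus_id", "label")])
  perm <- order(runif(nrow(d)))
  dp <- d[perm, ]
  res2 <- loio_cv(dp[, 1:4], dp[, c("image_id", "nucleus_id", "label")])
  key1 <- paste(res1$image_id, res1$nucleus_id)
  key2 <- paste(res2$image_id, res2$nucleus_id)
  expect_equal(res1$score, res2$score[match(key1, key2)], tolerance = 1e-9)
})

test_that("precision/recall curves have exact counts at every threshold", {
  scores <- c(0.9, 0.8, 0.4, 0.2)
  labels <- c("target", "target", "non_target", "target")
  curve <- pr_curve(scores, labels)
  # at threshold 0.5 (counted via the 0.8 point): TP=2, FP=0, FN=1
  i <- which(curve$threshold == 0.8)
  expect_equal(curve$tp[i], 2)
  expect_equal(curve$fp[i], 0)
  expect_equal(curve$fn[i], 1)
  expect_equal(curve$precision[i], 1)
  expect_equal(curve$recall[i], 2 / 3)
  # lowest threshold: recall 1, precision = prevalence
  j <- nrow(curve)
  expect_equal(curve$recall[j], 1)
  expect_equal(curve$precision[j], 3 / 4)
  expect_error(pr_curve(scores, rep("non_target", 4)), "no target")
})

test_that("curve counts equal a per-threshold recount on random data", {
  set.seed(23)
  for (i in 1:100) {
    n <- sample(5:50, 1)
    scores <- round(runif(n), 2)  # ties likely
    y <- rbinom(n, 1, 0.4)
    if (sum(y) == 0) y[1] <- 1
    curve <- pr_curve(scores, y)
    expect_equal(nrow(curve), length(unique(scores)))
    for (k in seq_len(nrow(curve))) {
      cnt <- pr_recount(scores, y, curve$threshold[k])
      expect_equal(c(curve$tp[k], curve$fp[k], curve$fn[k]), unname(cnt))
      expect_true(curve$recall[k] >= 0 && curve$recall[k] <= 1)
    }
    # recall is non-increasing in the threshold
    ord <- order(curve$threshold)
    expect_true(!is.unsorted(rev(curve$recall[ord])))
  }
})

test_that("threshold selection maximizes precision under the recall floor", {
  curve <- pr_curve(c(0.9, 0.8, 0.4, 0.2),
                    c("target", "target", "non_target", "target"))
  sel <- select_threshold(curve, 0.6)
  expect_equal(sel$threshold, 0.8)
  expect_equal(sel$precision, 1)
  expect_equal(sel$recall, 2 / 3)

  # recall floor 1.0: threshold is the minimum score among true targets
  sel1 <- select_threshold(curve, 1.0)
  expect_equal(sel1$threshold, 0.2)

  # lowering the floor never lowers the selected precision
  floors <- c(1.0, 0.9, 0.6, 0.3, 0.1)
  precs <- vapply(floors, function(f) select_threshold(curve, f)$precision, 0)
  expect_true(!is.unsorted(precs))

  expect_error(select_threshold(curve, 1), NA)
})
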