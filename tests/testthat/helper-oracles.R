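# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's own code paths.

# stack-based flood fill labeling
flood_fill_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 4) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  }
  cur <- 0L
  for (cc in seq_len(nc)) for (rr in seq_len(nr)) {
    if (!mask[rr, cc] || lab[rr, cc] != 0L) next
    cur <- cur + 1L
    stack <- list(c(rr, cc))
    lab[rr, cc] <- cur
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (d in nb) {
        r2 <- p[1] + d[1]; c2 <- p[2] + d[2]
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
            mask[r2, c2] && lab[r2, c2] == 0L) {
          lab[r2, c2] <- cur
          stack[[length(stack) + 1]] <- c(r2, c2)
        }
      }
    }
  }
  lab
}

# sorted multiset of component areas (label-numbering independent)
component_areas <- function(lab) sort(tabulate(lab[lab > 0]))

# dense direct 2-D Gaussian convolution with symmetric-reflection padding
dense_gaussian_blur <- function(x, sigma) {
  radius <- ceiling(4 * sigma)
  k1 <- exp(-((-radius:radius)^2) / (2 * sigma^2))
  k1 <- k1 / sum(k1)
  k2 <- outer(k1, k1)
  n <- nrow(x); m <- ncol(x)
  ridx <- c(pmin(pmax(radius:1, 1), n), 1:n,
            pmin(pmax(n - seq_len(radius) + 1, 1), n))
  cidx <- c(pmin(pmax(radius:1, 1), m), 1:m,
            pmin(pmax(m - seq_len(radius) + 1, 1), m))
  xp <- x[ridx, cidx]
  out <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    out[i, j] <- sum(k2 * xp[i:(i + 2 * radius), j:(j + 2 * radius)])
  }
  out
}

# symmetric normalized GLCM of one window by explicit pair enumeration
glcm_enumerate <- function(qwin, levels, dr, dc) {
  nr <- nrow(qwin); nc <- ncol(qwin)
  g <- matrix(0, levels, levels)
  for (cc in seq_len(nc)) for (rr in seq_len(nr)) {
    r2 <- rr + dr; c2 <- cc + dc
    if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
      a <- qwin[rr, cc] + 1; b <- qwin[r2, c2] + 1
      g[a, b] <- g[a, b] + 1
      g[b, a] <- g[b, a] + 1
    }
  }
  g / sum(g)
}

glcm_stats_direct <- function(p) {
  lv <- nrow(p)
  i <- matrix(rep(0:(lv - 1), lv), lv)
  j <- t(i)
  mi <- sum(p * i); mj <- sum(p * j)
  vi <- sum(p * (i - mi)^2); vj <- sum(p * (j - mj)^2)
  list(contrast = sum(p * (i - j)^2),
       energy = sum(p^2),
       homogeneity = sum(p / (1 + (i - j)^2)),
       entropy = -sum(ifelse(p > 0, p * log2(p), 0)),
       correlation = if (vi > 1e-12 && vj > 1e-12)
         sum(p * (i - mi) * (j - mj)) / sqrt(vi * vj) else 0)
}

# windowed histogram entropy in bits, direct
entropy_direct <- function(win, bins, lo, hi) {
  span <- if (hi > lo) hi - lo else 1
  b <- floor((win - lo) / span * bins)
  b[b >= bins] <- bins - 1
  b[b < 0] <- 0
  p <- tabulate(b + 1, bins) / length(win)
  -sum(ifelse(p > 0, p * log2(p), 0))
}

# per-threshold recount of TP/FP/FN by direct comparison
pr_recount <- function(scores, y, threshold) {
  pred <- scores >= threshold
  c(tp = sum(pred & y == 1), fp = sum(pred & y == 0),
    fn = sum(!pred & y == 1))
}

# Fleiss kappa and its large-sample SE term by term from the count table
fleiss_direct <- function(counts) {
  n <- nrow(counts); k <- sum(counts[1, ])
  pj <- colSums(counts) / (n * k)
  pbar <- mean(sapply(seq_len(n), function(i) {
    sum(counts[i, ] * (counts[i, ] - 1)) / (k * (k - 1))
  }))
  pe <- sum(pj^2)
  kappa <- (pbar - pe) / (1 - pe)
  qj <- pj * (1 - pj)
  se <- sqrt(2 / (n * k * (k - 1))) *
    sqrt(sum(qj)^2 - sum(qj * (1 - 2 * pj))) / sum(qj)
  list(kappa = kappa, se = se)
}

# steer the second-derivative filter over discretized angles and return the
# along-ridge orientation (perpendicular to the most negative response)
steer_orientation <- function(rxx, rxy, ryy) {
  th <- seq(0, pi, length.out = 361)[-361]
  resp <- rxx * cos(th)^2 + 2 * rxy * sin(th) * cos(th) + ryy * sin(th)^2
  (th[which.min(resp)] + pi / 2) %% pi
}

rot90 <- function(m) t(m)[, nrow(m):1, drop = FALSE] # counterclockwise

gaussian_kernel_oracle <- function(sigma) {
  radius <- ceiling(4 * sigma)
  k <- exp(-((-radius:radius)^2) / (2 * sigma^2))
  k / sum(k)
}
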