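# Separable convolution with symmetric (reflective) boundary handling.
# Kept in R: each pass is a shift-accumulate over BLAS-friendly matrix
# slices, fast enough for the image sizes this package targets.

gaussian_kernel1d <- function(sigma, radius = ceiling(4 * sigma)) {
  stopifnot(sigma > 0)
  k <- exp(-((-radius:radius)^2) / (2 * sigma^2))
  k / sum(k)
}

# first and second derivative-of-Gaussian kernels (unnormalized amplitude)
gaussian_deriv1d <- function(sigma, order, radius = ceiling(4 * sigma)) {
  t <- -radius:radius
  g <- exp(-t^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (order == 0) return(g)
  if (order == 1) return(-t / sigma^2 * g)
  if (order == 2) return((t^2 - sigma^2) / sigma^4 * g)
  stop("order must be 0, 1 or 2")
}

# symmetric (half-sample) reflection indices, clamped for tiny images
reflect_idx <- function(n, p) {
  left <- pmin(pmax(p:1, 1L), n)
  right <- pmin(pmax(n - seq_len(p) + 1L, 1L), n)
  c(left, seq_len(n), right)
}

conv1_rows <- function(x, k) {
  p <- (length(k) - 1L) %/% 2L
  n <- nrow(x)
  xp <- x[reflect_idx(n, p), , drop = FALSE]
  out <- matrix(0, n, ncol(x))
  for (j in seq_along(k)) {
    out <- out + k[j] * xp[(j - 1L) + seq_len(n), , drop = FALSE]
  }
  out
}

# 2-D convolution with separable row/col kernels, reflective boundary
conv2_sep <- function(x, krow, kcol = krow) {
  t(conv1_rows(t(conv1_rows(x, krow)), kcol))
}

gaussian_blur <- function(x, sigma) {
  conv2_sep(x, gaussian_kernel1d(sigma))
}
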