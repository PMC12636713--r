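# Fixtures and independent oracle implementations used across the suite.
# Oracles are deliberately written as plain brute-force code, independent
# of the package's implementation paths.

# rasterize a filled disk; returns pixel coordinates (rows, cols)
disk_pixels <- function(radius, cy = radius + 11, cx = radius + 11) {
  n <- ceiling(2 * radius + 22)
  g <- expand.grid(r = seq_len(n), c = seq_len(n))
  sel <- (g$r - cy)^2 + (g$c - cx)^2 <= radius^2
  list(rows = g$r[sel], cols = g$c[sel], dim = c(n, n))
}

# binary raster with a filled disk
disk_mask <- function(radius, n = ceiling(2 * radius + 22),
                      cy = n / 2, cx = n / 2) {
  m <- matrix(FALSE, n, n)
  g <- expand.grid(r = seq_len(n), c = seq_len(n))
  m[cbind(g$r, g$c)] <- (g$r - cy)^2 + (g$c - cx)^2 <= radius^2
  m
}

# exhaustive-scan Otsu oracle on integer 8-bit data: tries every cut
# between adjacent gray levels and maximizes between-class variance,
# computed directly from the pixel values
otsu_oracle_8bit <- function(v8) {
  best <- -Inf; best_cut <- NA
  for (cut in 0:254) {
    lo <- v8[v8 <= cut]; hi <- v8[v8 > cut]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(v8); w1 <- 1 - w0
    bcv <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (bcv > best) { best <- bcv; best_cut <- cut }
  }
  best_cut
}

# brute-force morphometry from first principles, using a different code
# path (covariance matrix + eigen decomposition)
brute_features <- function(rows, cols) {
  a <- length(rows)
  cy <- sum(rows) / a; cx <- sum(cols) / a
  msd <- sum((rows - cy)^2 + (cols - cx)^2) / a
  ecc <- 0
  if (a > 1) {
    cv <- stats::cov(cbind(cols, rows)) * (a - 1) / a
    ev <- sort(eigen(cv, symmetric = TRUE)$values, decreasing = TRUE)
    if (ev[1] > 0) ecc <- sqrt(max(0, 1 - ev[2] / ev[1]))
  }
  list(area = a, centroid_x = cx, centroid_y = cy,
       compactness = 2 * pi * msd / a,
       equiv_diam = 2 * sqrt(a / pi), eccentricity = ecc)
}

# random connected blob: union of a few overlapping disks
random_blob <- function(seed) {
  set.seed(seed)
  n <- 80
  m <- matrix(FALSE, n, n)
  cy <- runif(1, 30, 50); cx <- runif(1, 30, 50)
  g <- expand.grid(r = seq_len(n), c = seq_len(n))
  for (k in 1:sample(2:5, 1)) {
    r <- runif(1, 4, 12)
    oy <- cy + rnorm(1, 0, 6); ox <- cx + rnorm(1, 0, 6)
    m[cbind(g$r, g$c)] <- m[cbind(g$r, g$c)] |
      ((g$r - oy)^2 + (g$c - ox)^2 <= r^2)
  }
  which(m, arr.ind = TRUE)
}

# exact signed-rank two-sided p by enumeration over all 2^n sign flips,
# mirroring the exact-branch tail convention
wilcoxon_exact_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.numeric(signs %*% r)
  mu <- n * (n + 1) / 4
  p <- if (v_obs > mu) 2 * mean(vs >= v_obs) else 2 * mean(vs <= v_obs)
  min(1, p)
}

# small five-channel stack of constant rasters
const_stack <- function(vals, n = 16) {
  channel_stack(lapply(vals, function(v) matrix(v, n, n)))
}
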