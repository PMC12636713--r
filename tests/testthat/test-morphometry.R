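# Shape features: the circle-anchored compactness, moments-based
# eccentricity, weighted perimeter and masked intensity means.

test_that("compactness anchors: disk = 1, pixel = 0, line from closed form", {
  d <- disk_pixels(50)
  expect_equal(compactness(d$rows, d$cols), 1, tolerance = 0.01)
  expect_equal(compactness(5, 7), 0)
  # straight 1-px line of length 100: brute-force pixel enumeration gives
  # 2*pi * mean squared distance / length
  rows <- rep(1, 100); cols <- 1:100
  oracle <- 2 * pi * mean((cols - mean(cols))^2) / 100
  expect_equal(compactness(rows, cols), oracle)
  expect_equal(oracle, 52.35, tolerance = 0.01)
})

test_that("compactness is invariant to translation, 90-degree rotation and scale", {
  b <- random_blob(3)
  r <- b[, 1]; c <- b[, 2]
  c0 <- compactness(r, c)
  expect_equal(compactness(r + 13, c - 7), c0)
  expect_equal(compactness(c, -r), c0)        # 90-degree rotation
  d20 <- disk_pixels(20); d60 <- disk_pixels(60)
  c20 <- compactness(d20$rows, d20$cols)
  c60 <- compactness(d60$rows, d60$cols)
  expect_lt(abs(c20 - c60) / c60, 0.03)
})

test_that("adding a thin process to a disk strictly increases compactness", {
  d <- disk_pixels(20)
  base <- compactness(d$rows, d$cols)
  rows <- c(d$rows, rep(31, 40))
  cols <- c(d$cols, max(d$cols) + (1:40))
  expect_gt(compactness(rows, cols), base)
  expect_gt(compactness(rows, cols), 1)
})

test_that("eccentricity matches closed-form moments", {
  d <- disk_pixels(30)
  expect_lt(eccentricity(d$rows, d$cols), 0.05)
  g <- expand.grid(r = 1:10, c = 1:100)        # 100 x 10 rectangle
  # closed form for a rectangle a x b: ecc = sqrt(1 - (b/a)^2)
  expect_equal(eccentricity(g$r, g$c), sqrt(1 - (10 / 100)^2),
               tolerance = 0.005)
})

test_that("equivalent diameter and perimeter behave on disks", {
  d <- disk_pixels(20)
  expect_equal(equivalent_diameter(length(d$rows)), 40, tolerance = 1)
  p <- perimeter(d$rows, d$cols)
  expect_equal(p, 2 * pi * 20, tolerance = 2 * pi * 20 * 0.08)
})

test_that("all features match a brute-force oracle on 50 random blobs", {
  for (seed in 1:50) {
    b <- random_blob(seed)
    r <- b[, 1]; c <- b[, 2]
    o <- brute_features(r, c)
    expect_equal(compactness(r, c), o$compactness, tolerance = 1e-12)
    expect_equal(eccentricity(r, c), o$eccentricity, tolerance = 1e-8)
    expect_equal(equivalent_diameter(length(r)), o$equiv_diam)
  }
})

test_that("perimeter agrees with the EBImage implementation on random blobs", {
  for (seed in c(2, 9, 17, 33)) {
    b <- random_blob(seed)
    m <- matrix(0, 80, 80); m[b] <- 1
    ours <- perimeter(b[, 1], b[, 2])
    ref <- EBImage::computeFeatures.shape(m)[1, "s.perimeter"]
    expect_equal(ours, ref, tolerance = 0.15 * ref)
  }
})

test_that("measure_intensity is the masked arithmetic mean per channel", {
  st <- const_stack(list(CD74 = 7, IBA1 = 0), 16)
  expect_equal(measure_intensity(1:4, 1:4, st),
               c(CD74 = 7, IBA1 = 0))
  half <- matrix(0, 16, 16); half[, 9:16] <- 10
  st2 <- channel_stack(list(X = half))
  expect_equal(unname(measure_intensity(rep(8, 16), 1:16, st2)), 5)
  set.seed(4)
  rnd <- matrix(runif(256), 16, 16)
  st3 <- channel_stack(list(R = rnd))
  r <- sample(1:16, 30, TRUE); c <- sample(1:16, 30, TRUE)
  expect_equal(unname(measure_intensity(r, c, st3)),
               mean(rnd[cbind(r, c)]))
  expect_error(measure_intensity(1, 1, st3, channels = "Z"),
               "configuration error")
})

test_that("measure_objects emits one consistent record per labeled object", {
  lab <- matrix(0L, 40, 40)
  lab[5:14, 5:14] <- 1L                        # 10x10 square
  lab[30, 5:24] <- 2L                          # 1x20 line
  tab <- measure_objects(label_map(lab), const_stack(list(M = 0.5), 40))
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$area_px, c(100, 20))
  expect_equal(tab$centroid_x, c(9.5, 14.5))
  expect_equal(tab$mean_M, c(0.5, 0.5))
  o1 <- brute_features(rep(5:14, each = 10), rep(5:14, times = 10))
  expect_equal(tab$compactness[1], o1$compactness)
})
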