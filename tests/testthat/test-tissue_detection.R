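# Tissue delineation from the 4X pair, gray/white segmentation and the
# 95% gray-matter tile gate.

make_slide <- function(n = 200, disk_r = 70) {
  bf <- matrix(0.9, n, n) + matrix(rnorm(n * n, 0, 0.01), n, n)
  dapi <- matrix(0.02, n, n) + matrix(rnorm(n * n, 0, 0.01), n, n)
  m <- disk_mask(disk_r, n)
  bf[m] <- 0.35
  dapi[m] <- 0.5
  list(bf = bf, dapi = dapi, mask = m)
}

test_that("tissue is the intersection of dark brightfield and bright DAPI", {
  set.seed(1)
  s <- make_slide()
  t <- detect_tissue(s$bf, s$dapi, min_area_mm2 = 0.001)
  jac <- sum(t & s$mask) / sum(t | s$mask)
  expect_gt(jac, 0.98)
})

test_that("disjoint brightfield and DAPI foregrounds give an empty mask", {
  set.seed(2)
  n <- 200
  bf <- matrix(0.9, n, n) + matrix(rnorm(n * n, 0, 0.005), n, n)
  dapi <- matrix(0.02, n, n) + matrix(rnorm(n * n, 0, 0.005), n, n)
  bf[1:100, ] <- 0.3        # dark only in the top half
  dapi[150:200, ] <- 0.5    # DAPI only in the bottom quarter
  expect_warning(t <- detect_tissue(bf, dapi, min_area_mm2 = 0.001),
                 "empty")
  expect_false(any(t))
})

test_that("gray matter is the darker brightfield class within tissue", {
  set.seed(3)
  n <- 120
  bf <- matrix(0.9, n, n)
  tissue <- matrix(FALSE, n, n); tissue[20:100, 20:100] <- TRUE
  bf[20:100, 20:60] <- 0.3    # darker plateau
  bf[20:100, 61:100] <- 0.6   # brighter plateau
  m <- segment_gray_matter(bf, tissue)
  expect_true(all(m$labels[20:100, 20:60] == 2L))
  expect_true(all(m$labels[20:100, 61:100] == 1L))
  expect_true(all(m$labels[!tissue] == 0L))
  # partition invariant: gray + white = tissue
  expect_equal(sum(m$labels > 0L), sum(tissue))
  expect_error(segment_gray_matter(matrix(0.5, 10, 10),
                                   matrix(TRUE, 10, 10)),
               "degenerate")
})

test_that("the gray-matter tile gate is strict at 95%", {
  lab <- matrix(2L, 100, 100)          # all gray, 4X grid
  mask <- structure(list(labels = lab, scale_to_tile = 5,
                         pixel_size_um = 1.625), class = "TissueMask")
  r <- tile_gray_fraction(mask, c(0, 0), c(100, 100))
  expect_equal(r$fraction, 1)
  expect_true(r$accepted)
  # 50/50 straddle of a gray/white boundary
  lab2 <- lab; lab2[, 51:100] <- 1L
  mask2 <- structure(list(labels = lab2, scale_to_tile = 5,
                          pixel_size_um = 1.625), class = "TissueMask")
  r2 <- tile_gray_fraction(mask2, c(150, 0), c(200, 200))
  expect_equal(r2$fraction, 0.5)
  expect_false(r2$accepted)
  # fraction exactly 0.95 is rejected (strict inequality)
  lab3 <- lab; lab3[, 96:100] <- 1L
  mask3 <- structure(list(labels = lab3, scale_to_tile = 5,
                          pixel_size_um = 1.625), class = "TissueMask")
  r3 <- tile_gray_fraction(mask3, c(0, 0), c(500, 500))
  expect_equal(r3$fraction, 0.95)
  expect_false(r3$accepted)
  expect_error(tile_gray_fraction(mask, c(490, 0), c(100, 100)),
               "coordinate error")
})

test_that("accepted-tile count is monotone non-increasing in the cutoff", {
  lab <- matrix(2L, 100, 100); lab[, 81:100] <- 1L
  mask <- structure(list(labels = lab, scale_to_tile = 5,
                         pixel_size_um = 1.625), class = "TissueMask")
  origins <- lapply(seq(0, 400, by = 50), function(x) c(x, 0))
  counts <- vapply(c(0.5, 0.8, 0.95, 0.99), function(cut)
    sum(vapply(origins, function(o)
      tile_gray_fraction(mask, o, c(100, 100), cutoff = cut)$accepted,
      logical(1))), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("generated sections are recovered: masks, gray area, gating", {
  sec <- generate_section(seed = 11)
  tissue <- detect_tissue(sec$brightfield_4x, sec$dapi_4x)
  truth <- sec$truth$tissue_labels
  jac <- sum(tissue & truth > 0) / sum(tissue | truth > 0)
  expect_gte(jac, 0.95)
  mask <- segment_gray_matter(sec$brightfield_4x, tissue)
  jg <- sum(mask$labels == 2 & truth == 2) / sum(mask$labels == 2 | truth == 2)
  jw <- sum(mask$labels == 1 & truth == 1) / sum(mask$labels == 1 | truth == 1)
  expect_gte(jg, 0.9)
  expect_gte(jw, 0.9)
  # total gray-matter area within 5% of ground truth
  expect_lt(abs(gray_area_mm2(mask) - sec$truth$gray_area_mm2) /
              sec$truth$gray_area_mm2, 0.05)
  # boundary-straddling tiles sit at 0.5, interior tiles at 1.0
  shape <- rep(sec$truth$tile_px, 2)
  fr <- vapply(seq_len(nrow(sec$truth$tile_origins)), function(k)
    tile_gray_fraction(mask, sec$truth$tile_origins[k, ], shape)$fraction,
    numeric(1))
  expect_equal(fr[5:6], c(0.5, 0.5), tolerance = 0.05)
  expect_true(all(fr[1:4] > 0.95))
})
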