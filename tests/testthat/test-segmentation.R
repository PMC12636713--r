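# Object segmentation: primary-object identification with declumping,
# the microglia two-step, tubeness enhancement, astrocytes and pTau.

noisy <- function(img, seed = 1, sd = 0.005) {
  set.seed(seed)
  pmax(img + matrix(rnorm(length(img), 0, sd), nrow(img), ncol(img)), 0)
}

two_disks <- function(centers_dist, r = 15, n = 120, value = 0.6) {
  img <- matrix(0.02, n, n)
  g <- expand.grid(rr = 1:n, cc = 1:n)
  c1 <- c(n / 2, n / 2 - centers_dist / 2)
  c2 <- c(n / 2, n / 2 + centers_dist / 2)
  sel <- ((g$rr - c1[1])^2 + (g$cc - c1[2])^2 <= r^2) |
    ((g$rr - c2[1])^2 + (g$cc - c2[2])^2 <= r^2)
  img[cbind(g$rr, g$cc)] <- ifelse(sel, value, img[cbind(g$rr, g$cc)])
  img
}

test_that("identify_primary_objects finds separated disks and filters by size", {
  img <- noisy(two_disks(35))          # 5 px gap between disk rims
  lm <- identify_primary_objects(img, c(18, 80), "otsu", "none")
  expect_equal(lm$n_objects, 2L)
  # diameter-10 disk is excluded by the (18, 80) range
  small <- matrix(0.02, 80, 80)
  g <- expand.grid(rr = 1:80, cc = 1:80)
  small[cbind(g$rr, g$cc)][(g$rr - 40)^2 + (g$cc - 40)^2 <= 25] <- 0.6
  lm2 <- identify_primary_objects(noisy(small), c(18, 80), "otsu", "none")
  expect_equal(lm2$n_objects, 0L)
  # empty foreground is an empty map, not an error
  lm3 <- identify_primary_objects(matrix(0.5, 50, 50), c(18, 80),
                                  "robust_background", "none")
  expect_equal(lm3$n_objects, 0L)
})

test_that("shape declumping separates overlapping disks along the neck", {
  img <- noisy(two_disks(25))          # overlapping: centers 25 px, d = 30
  merged <- identify_primary_objects(img, c(18, 80), "otsu", "none")
  expect_equal(merged$n_objects, 1L)
  split <- identify_primary_objects(img, c(18, 80), "otsu", "shape")
  expect_equal(split$n_objects, 2L)
  tab <- measure_objects(split)
  # dividing line roughly in the middle: similar areas on the two sides
  expect_lt(abs(tab$area_px[1] - tab$area_px[2]) / sum(tab$area_px), 0.2)
})

test_that("segmentation is deterministic", {
  img <- noisy(two_disks(25), seed = 3)
  a <- identify_primary_objects(img, c(18, 80), "otsu", "shape")
  b <- identify_primary_objects(img, c(18, 80), "otsu", "shape")
  expect_identical(a$labels, b$labels)
})

test_that("microglia nuclei are gated by size and pooled IBA1 mean + 2 SD", {
  # 5 x 5 grid of identical nuclei; one has bright IBA1
  n <- 300
  dapi <- matrix(0.02, n, n); iba1 <- matrix(0.02, n, n)
  g <- expand.grid(rr = 1:n, cc = 1:n)
  centers <- expand.grid(y = seq(30, 270, by = 60), x = seq(30, 270, by = 60))
  for (i in seq_len(nrow(centers))) {
    sel <- (g$rr - centers$y[i])^2 + (g$cc - centers$x[i])^2 <= 12^2
    dapi[cbind(g$rr, g$cc)][sel] <- 0.6
    iba1[cbind(g$rr, g$cc)][sel] <- if (i == 13) 0.7 else 0.05
  }
  dapi <- noisy(dapi, 5); iba1 <- noisy(iba1, 6)
  nuc <- identify_primary_objects(dapi, c(18, 80), "otsu", "shape")
  expect_equal(nuc$n_objects, 25L)
  sel <- select_microglia_nuclei(nuc, iba1)
  expect_equal(sel$labels$n_objects, 1L)
  ctr <- measure_objects(sel$labels)
  expect_equal(c(ctr$centroid_x, ctr$centroid_y), c(150, 150), tolerance = 2)
  # all-equal IBA1 selects nothing (nothing exceeds mean + 2 SD)
  sel0 <- select_microglia_nuclei(nuc, matrix(0.3, n, n))
  expect_equal(sel0$labels$n_objects, 0L)
  # the equivalent-diameter bound is strict
  tab <- measure_objects(nuc, channel_stack(list(IBA1 = iba1)))
  expect_true(all(sel$table$equiv_diam_px < 40))
  # fewer than 3 nuclei in the population is an error
  tiny <- label_map(matrix(c(rep(0L, 50), rep(1L, 14)), 8, 8))
  expect_error(select_microglia_nuclei(tiny, matrix(0.1, 8, 8)),
               "insufficient population")
})

test_that("tubeness responds to ridges, not to flats or large blobs", {
  n <- 120
  img <- matrix(0.02, n, n)
  img[60, 20:100] <- 0.8               # bright thin line
  tub <- enhance_tubeness(img, 4)
  line_resp <- mean(tub[60, 40:80])
  flat_resp <- mean(tub[20, 40:80])
  expect_gt(line_resp, 5 * max(flat_resp, 1e-12))
  expect_true(all(enhance_tubeness(matrix(0.5, 40, 40), 4) == 0))
  big <- matrix(0.02, 200, 200)
  g <- expand.grid(rr = 1:200, cc = 1:200)
  big[cbind(g$rr, g$cc)][(g$rr - 100)^2 + (g$cc - 100)^2 <= 60^2] <- 0.8
  tub2 <- enhance_tubeness(big, 4)
  expect_lt(mean(tub2[90:110, 90:110]), 0.05 * max(tub2))
})

test_that("fragments link to the nearest nucleus within 60 px only", {
  n <- 200
  nucl <- matrix(0L, n, n)
  g <- expand.grid(rr = 1:n, cc = 1:n)
  nucl[cbind(g$rr, g$cc)][(g$rr - 100)^2 + (g$cc - 60)^2 <= 10^2] <- 1L
  mk_frag <- function(cx) {
    f <- matrix(0L, n, n)
    f[cbind(g$rr, g$cc)][(g$rr - 100)^2 + (g$cc - cx)^2 <= 6^2] <- 1L
    label_map(f, "microglia_fragment")
  }
  nl <- label_map(nucl, "microglia_nucleus")
  f59 <- mk_frag(60 + 59)
  near <- assemble_microglia(f59, nl, 60)
  expect_equal(near$labels$n_objects, 1L)
  expect_equal(near$assignment, 1L)
  expect_equal(near$objects$area_px,
               sum(nucl) + sum(f59$labels > 0))        # union of both masks
  far <- assemble_microglia(mk_frag(60 + 61), nl, 60)
  expect_true(is.na(far$assignment))
  expect_equal(far$objects$area_px, sum(nucl))         # fragment dropped
  # no nuclei: zero microglia, fragments dropped
  none <- assemble_microglia(mk_frag(100), label_map(matrix(0L, n, n),
                                                     "microglia_nucleus"), 60)
  expect_equal(none$labels$n_objects, 0L)
})

test_that("an equidistant fragment goes to the lower nucleus label", {
  n <- 200
  nucl <- matrix(0L, n, n)
  g <- expand.grid(rr = 1:n, cc = 1:n)
  nucl[cbind(g$rr, g$cc)][(g$rr - 100)^2 + (g$cc - 50)^2 <= 8^2] <- 1L
  nucl[cbind(g$rr, g$cc)][(g$rr - 100)^2 + (g$cc - 150)^2 <= 8^2] <- 2L
  frag <- matrix(0L, n, n)
  frag[cbind(g$rr, g$cc)][(g$rr - 100)^2 + (g$cc - 100)^2 <= 5^2] <- 1L
  res <- assemble_microglia(label_map(frag, "microglia_fragment"),
                            label_map(nucl, "microglia_nucleus",
                                      relabel = FALSE), 60)
  expect_equal(res$assignment, 1L)
})

test_that("no assigned fragment lies farther than the link radius", {
  tl <- generate_tile(sim_tile_params(microglia_per_mm2 = 250,
                                      other_nuclei_per_mm2 = 1200),
                      seed = 31)
  res <- segment_tile(tl$stack, astrocytes = FALSE)
  frag_tab <- measure_objects(res$fragments)
  nuc_tab <- measure_objects(res$microglia_nuclei)
  asg <- assemble_microglia(res$fragments, res$microglia_nuclei)$assignment
  for (i in which(!is.na(asg))) {
    j <- asg[i]
    d <- sqrt((frag_tab$centroid_x[i] - nuc_tab$centroid_x[j])^2 +
                (frag_tab$centroid_y[i] - nuc_tab$centroid_y[j])^2)
    expect_lte(d, 60)
  }
  # one microglia per selected nucleus
  expect_equal(res$microglia$labels$n_objects,
               res$microglia_nuclei$n_objects)
})

test_that("astrocyte segmentation recovers stars over nuclei and gates on DAPI", {
  tl <- generate_tile(sim_tile_params(microglia_per_mm2 = 0,
                                      other_nuclei_per_mm2 = 300,
                                      astrocytes_per_mm2 = 150,
                                      ptau_threads_per_mm2 = 0,
                                      ptau_tangles_per_mm2 = 0), seed = 3)
  truth <- tl$truth$cells
  tas <- truth[truth$class == "astrocyte", ]
  nuc <- identify_primary_objects(tl$stack$channels$DAPI, c(18, 80),
                                  "robust_background", "shape")
  ast <- segment_astrocytes(tl$stack$channels$GFAP, nuc, stack = tl$stack)
  expect_equal(ast$labels$n_objects, nrow(tas))
  d <- sqrt(outer(ast$objects$centroid_y, tas$y, "-")^2 +
              outer(ast$objects$centroid_x, tas$x, "-")^2)
  expect_equal(sum(apply(d, 2, min) < 25), nrow(tas))
  # >= 80% of strongly GFAP-positive pixels belong to astrocyte objects
  gf <- tl$stack$channels$GFAP > 0.3
  expect_gte(mean(ast$labels$labels[gf] > 0), 0.8)
  # without nuclei the DAPI gate removes everything
  ast0 <- segment_astrocytes(tl$stack$channels$GFAP,
                             label_map(matrix(0L, 510, 510)))
  expect_equal(ast0$labels$n_objects, 0L)
})

test_that("pTau segmentation counts threads and tangles on a built tile", {
  set.seed(77)
  n <- 510
  at8 <- matrix(0.02, n, n)
  pos <- expand.grid(y = c(80, 200, 320, 440), x = c(80, 230, 380))
  for (i in 1:8)                        # 8 curvilinear threads
    at8 <- gliaquant:::paint_walk(at8, pos$y[i], pos$x[i],
                                  runif(1, 0, 2 * pi), 120, 1.5, 0.6,
                                  jitter_sd = 0.1)
  for (i in 9:10) {                     # 2 blob tangles
    at8 <- gliaquant:::paint_disk(at8, pos$y[i], pos$x[i], 20, 0.7)
    at8 <- gliaquant:::paint_disk(at8, pos$y[i] + 8, pos$x[i] + 6, 12, 0.7)
  }
  at8 <- gliaquant:::finish_channel(at8, 0.7, 0.008)
  lm <- segment_ptau(at8)
  expect_gte(lm$n_objects, 9L)
  expect_lte(lm$n_objects, 11L)
  cls <- classify_ptau(measure_objects(lm))
  expect_gte(cls$counts[["tangles"]], 1)
  expect_gte(cls$counts[["threads"]], 7)
  # a simple flat tile with one bright blob gives exactly one object
  one <- matrix(0.02, 200, 200)
  one <- gliaquant:::paint_disk(one, 100, 100, 15, 0.7)
  one <- gliaquant:::finish_channel(one, 0.7, 0.005)
  expect_equal(segment_ptau(one)$n_objects, 1L)
  # a blob of equivalent diameter ~100 px is excluded by the 1-80 gate
  big <- matrix(0.02, 300, 300)
  big <- gliaquant:::paint_disk(big, 150, 150, 50, 0.7)
  big <- gliaquant:::finish_channel(big, 0.7, 0.005)
  expect_equal(segment_ptau(big)$n_objects, 0L)
})

test_that("pTau thread/tangle classification partitions by the printed areas", {
  obj <- data.frame(area_px = c(899, 900, 950, 100, 500, 2000, 12000, 10000))
  cls <- classify_ptau(obj)
  expect_equal(cls$objects$ptau_class,
               c("thread", "tangle", "tangle", "thread", "thread",
                 "tangle", "unclassified", "unclassified"))
  part <- classify_ptau(data.frame(area_px = c(100, 500, 2000, 12000)))
  expect_equal(unname(part$counts), c(2, 1, 1))
  # counts partition the objects; area occupied covers all of them
  expect_equal(sum(part$counts), 4)
  expect_equal(part$area_occupied_mm2,
               sum(c(100, 500, 2000, 12000)) * 0.325^2 / 1e6)
})
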