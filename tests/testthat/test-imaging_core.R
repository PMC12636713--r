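# Thresholding primitives, the ChannelStack/LabelMap data model, and I/O.

test_that("Otsu threshold separates a two-level image and rejects constants", {
  img <- matrix(c(rep(0, 50), rep(100, 50)), 10, 10)
  t <- otsu_threshold(img)
  expect_gt(t, 0)
  expect_lt(t, 100)
  expect_identical(img > t, img == 100)
  expect_error(otsu_threshold(matrix(5, 4, 4)), "degenerate|constant")
})

test_that("Otsu threshold equals the exhaustive between-class-variance scan", {
  set.seed(42)
  for (rep in 1:8) {
    v8 <- pmin(pmax(round(c(rnorm(5000, 40, 10), rnorm(5000, 180, 10))), 0), 255)
    img <- matrix(v8 / 255, 100, 100)
    cut <- otsu_oracle_8bit(v8)            # foreground = values > cut
    t <- otsu_threshold(img)
    # identical partition of the pixel values
    expect_identical(img > t, matrix(v8 > cut, 100, 100))
  }
})

test_that("robust background threshold matches direct enumeration and edge cases", {
  # constant image: threshold equals the constant for any multiplier
  expect_equal(robust_background_threshold(matrix(3.5, 10, 10),
                                           sd_multiplier = 7), 3.5)
  # 90 pixels at 10, 10 at 200, 5%/5% trims: direct enumeration oracle
  v <- c(rep(10, 90), rep(200, 10))
  s <- sort(v)[6:95]
  expect_equal(robust_background_threshold(v, 0.05, 0.05, 2),
               mean(s) + 2 * sd(s))
  # multiplier 0 returns the trimmed mean
  expect_equal(robust_background_threshold(v, 0.05, 0.05, 0), mean(s))
  expect_error(robust_background_threshold(1:10, 0.5, 0.5), "< 1")
})

test_that("robust background threshold is order-invariant and monotone in k", {
  set.seed(1)
  v <- rlnorm(500)
  expect_equal(robust_background_threshold(v),
               robust_background_threshold(sample(v)))
  ks <- c(0, 0.5, 1, 2, 5, 20)
  ts <- vapply(ks, function(k)
    robust_background_threshold(v, sd_multiplier = k), numeric(1))
  expect_true(all(diff(ts) > 0))
})

test_that("ChannelStack validates dimensions, finiteness and pixel size", {
  ch <- list(DAPI = matrix(0.1, 8, 8), IBA1 = matrix(0.2, 8, 8))
  s <- channel_stack(ch)
  expect_s3_class(s, "ChannelStack")
  expect_equal(s$pixel_size_um, 0.325)
  expect_error(channel_stack(list(A = matrix(1, 4, 4), B = matrix(1, 5, 4))),
               "identical dimensions")
  expect_error(channel_stack(list(A = matrix(-1, 4, 4))), "negative")
  expect_error(channel_stack(list(A = matrix(NA_real_, 4, 4))), "non-finite")
  expect_error(channel_stack(ch, pixel_size_um = 0), "positive")
  expect_error(require_channels(s, c("DAPI", "CD74")), "configuration error")
})

test_that("printed unit anchors hold at the 20X pixel scale", {
  expect_equal(px_to_um(60), 19.5)
  expect_equal(px_to_um(40), 13.0)
  expect_equal(um_to_px(19.5), 60)
})

test_that("label and tile TIFF I/O round-trips 16-bit data losslessly", {
  tmp <- withr::local_tempdir()
  lab <- matrix(0L, 20, 20); lab[3:6, 3:6] <- 1L; lab[12:15, 10:14] <- 2L
  lm <- label_map(lab, "nucleus")
  f <- file.path(tmp, "lab.tif")
  write_labelmap(lm, f)
  back <- read_labelmap(f, "nucleus")
  expect_identical(back$labels, lm$labels)
  expect_equal(back$n_objects, 2L)
  # intensity tiles on the 16-bit grid round-trip exactly
  set.seed(9)
  ch <- list(DAPI = matrix(sample(0:65535, 64, TRUE) / 65535, 8, 8),
             IBA1 = matrix(sample(0:65535, 64, TRUE) / 65535, 8, 8))
  s <- channel_stack(ch, tile_id = "t1")
  write_tile(s, file.path(tmp, "t1"))
  back2 <- read_tile(file.path(tmp, "t1"),
                     c(DAPI = "DAPI.tif", IBA1 = "IBA1.tif"))
  expect_equal(back2$channels$DAPI, ch$DAPI)
  expect_equal(back2$channels$IBA1, ch$IBA1)
  expect_error(read_tile(file.path(tmp, "t1"), c(CD74 = "CD74.tif")),
               "configuration error")
})

test_that("object tables round-trip through CSV, including empty tables", {
  tmp <- withr::local_tempdir()
  f <- file.path(tmp, "obj.csv")
  write_object_table(NULL, f)
  empty <- read_object_table(f)
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("tile_id", "label", "compactness", "flags") %in%
                    names(empty)))
  lab <- matrix(0L, 30, 30); lab[5:10, 5:10] <- 1L; lab[20:24, 18:25] <- 2L
  tab <- measure_objects(label_map(lab), const_stack(list(CD74 = 0.4), 30))
  write_object_table(tab, f)
  back <- read_object_table(f)
  expect_equal(back$area_px, tab$area_px)
  expect_equal(back$mean_CD74, tab$mean_CD74)
})
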