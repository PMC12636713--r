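# Per-tile image quality control: flag empty, blurry and
# debris-contaminated tiles before segmentation.

#' Mean absolute deviation of an intensity raster
#'
#' Mean over pixels of |I - median(I)|; near zero for empty tiles.
#'
#' @param img Numeric matrix.
#' @return Non-negative scalar.
#' @export
mean_absolute_deviation <- function(img) {
  v <- as.numeric(img)
  if (!length(v)) stop("empty raster")
  mean(abs(v - stats::median(v)))
}

#' Power log-log slope: a spectral blur metric
#'
#' Crops the raster to its largest centered square, computes the 2-D power
#' spectrum, radially averages it into log-spaced frequency bins over a
#' mid-frequency band, and returns the OLS slope of log(power) on
#' log(frequency). White noise gives a slope near 0; blurring makes the
#' slope more negative.
#'
#' @param img Numeric matrix, at least 64 x 64.
#' @param band Frequency band as a fraction of the Nyquist frequency
#'   (default `c(0.05, 0.45)`).
#' @param n_bins Number of log-spaced radial bins (default 32; stable at
#'   tile sizes from 64 to 1024 px).
#' @return Scalar slope (dimensionless); more negative = blurrier.
#' @export
power_loglog_slope <- function(img, band = c(0.05, 0.45), n_bins = 32L) {
  if (min(dim(img)) < 64L) stop("raster must be at least 64 x 64")
  s <- min(dim(img))
  r0 <- floor((nrow(img) - s) / 2); c0 <- floor((ncol(img) - s) / 2)
  m <- img[(r0 + 1):(r0 + s), (c0 + 1):(c0 + s)]
  if (all(m == 0)) stop("undefined metric: all-zero image")
  m <- m - mean(m)
  p <- Mod(stats::fft(m))^2
  f1 <- c(0:(s %/% 2), -((s - s %/% 2 - 1):1)) / s   # cycles per pixel
  fr <- sqrt(outer(f1^2, f1^2, "+"))
  nyq <- 0.5
  edges <- exp(seq(log(band[1] * nyq), log(band[2] * nyq),
                   length.out = n_bins + 1L))
  bin <- findInterval(fr, edges, rightmost.closed = TRUE)
  sel <- bin >= 1L & bin <= n_bins
  pw <- tapply(p[sel], bin[sel], mean)
  fc <- tapply(fr[sel], bin[sel], mean)
  ok <- pw > 0
  if (sum(ok) < 3L) stop("undefined metric: too few populated frequency bins")
  stats::coef(stats::lm(log(pw[ok]) ~ log(fc[ok])))[[2]]
}

#' Default QC policy
#'
#' Tile exclusion is traditionally done by visual inspection of the QC
#' metric distributions; this package replaces inspection with an explicit
#' config-driven rule. A tile is flagged only if its metric is beyond the
#' batch percentile cutoff *and* beyond a scale-free guard relative to the
#' batch median, so homogeneous defect-free batches are (almost always)
#' fully accepted while planted defects, which are gross outliers, are
#' caught:
#' \itemize{
#'   \item empty: IBA1 MAD below the `empty_mad_pctl` percentile and below
#'     `empty_mad_ratio` times the batch median (an empty tile carries only
#'     noise, a fraction of the typical signal);
#'   \item blurry: a focus channel's slope more negative than the
#'     `blur_pctl` percentile of that channel and more than
#'     `blur_slope_margin` below the channel median (defocus steepens the
#'     power spectrum by well over one unit of log-log slope);
#'   \item debris: a channel's Otsu threshold above the `debris_pctl`
#'     percentile, above `debris_otsu_ratio` times the channel median and
#'     above the absolute floor `debris_otsu_min` (bright debris forces
#'     the histogram cut far higher, on \[0, 1\]-normalized data, than
#'     ordinary staining ever does; the floor keeps sparse channels whose
#'     median threshold is near zero from flagging genuine content).
#' }
#'
#' @param empty_mad_pctl Lower percentile of IBA1 MAD (default 0.02).
#' @param blur_pctl Upper percentile of |power log-log slope| per focus
#'   channel (default 0.98).
#' @param debris_pctl Upper percentile of the per-channel Otsu threshold
#'   (default 0.98).
#' @param empty_mad_ratio,blur_slope_margin,debris_otsu_ratio Guard
#'   parameters (see above).
#' @param min_tiles Minimum batch size for percentile estimation; below it
#'   the absolute fallback thresholds are used (with a warning).
#' @param empty_mad_abs,blur_slope_abs,debris_otsu_abs Absolute fallback
#'   thresholds for small batches.
#' @return A list of class `qc_policy`.
#' @export
qc_policy <- function(empty_mad_pctl = 0.02, blur_pctl = 0.98,
                      debris_pctl = 0.98, empty_mad_ratio = 0.35,
                      blur_slope_margin = 1.5, debris_otsu_ratio = 1.25,
                      debris_otsu_min = 0.35, min_tiles = 20L,
                      empty_mad_abs = 0.0075, blur_slope_abs = -4.5,
                      debris_otsu_abs = 0.4) {
  # fallback absolutes assume intensities normalized to [0, 1]
  structure(list(empty_mad_pctl = empty_mad_pctl, blur_pctl = blur_pctl,
                 debris_pctl = debris_pctl,
                 empty_mad_ratio = empty_mad_ratio,
                 blur_slope_margin = blur_slope_margin,
                 debris_otsu_ratio = debris_otsu_ratio,
                 debris_otsu_min = debris_otsu_min,
                 min_tiles = min_tiles, empty_mad_abs = empty_mad_abs,
                 blur_slope_abs = blur_slope_abs,
                 debris_otsu_abs = debris_otsu_abs),
            class = "qc_policy")
}

#' Quality-control a batch of image tiles
#'
#' Computes the IBA1 mean absolute deviation, the power log-log slope of
#' IBA1/GFAP/DAPI and the per-channel Otsu threshold for every tile, then
#' applies the policy: `empty` if the IBA1 MAD falls below the batch
#' percentile, `blurry` if any focus channel's |slope| exceeds its upper
#' percentile, `debris` if any channel's Otsu threshold exceeds its upper
#' percentile (each combined with the robust-outlier guard, see
#' [qc_policy()]). A tile is accepted iff it carries no flag.
#'
#' @param tiles List of [channel_stack()] objects (>= 1).
#' @param policy A [qc_policy()].
#' @param focus_channels Channels screened for blur.
#' @param mad_channel Channel screened for emptiness.
#' @return Data frame with one row per tile: metrics, individual flags, a
#'   semicolon-joined `flags` string and `accepted`.
#' @export
qc_tiles <- function(tiles, policy = qc_policy(),
                     focus_channels = c("IBA1", "GFAP", "DAPI"),
                     mad_channel = "IBA1") {
  stopifnot(length(tiles) >= 1L)
  channels <- names(tiles[[1]]$channels)
  for (t in tiles) require_channels(t, union(mad_channel, focus_channels))
  n <- length(tiles)
  met <- data.frame(tile_id = vapply(tiles, function(t) t$tile_id,
                                     character(1)))
  met$mad <- vapply(tiles, function(t)
    mean_absolute_deviation(t$channels[[mad_channel]]), numeric(1))
  for (ch in focus_channels)
    met[[paste0("plls_", ch)]] <- vapply(tiles, function(t)
      power_loglog_slope(t$channels[[ch]]), numeric(1))
  for (ch in channels)
    met[[paste0("otsu_", ch)]] <- vapply(tiles, function(t)
      tryCatch(otsu_threshold(t$channels[[ch]]), error = function(e) 0),
      numeric(1))

  if (n < policy$min_tiles) {
    warning("fewer than ", policy$min_tiles,
            " tiles: using absolute fallback thresholds")
    flag_empty <- met$mad < policy$empty_mad_abs
    flag_blur <- Reduce(`|`, lapply(focus_channels, function(ch)
      met[[paste0("plls_", ch)]] < policy$blur_slope_abs))
    flag_debris <- Reduce(`|`, lapply(channels, function(ch)
      met[[paste0("otsu_", ch)]] > policy$debris_otsu_abs))
  } else {
    q_mad <- stats::quantile(met$mad, policy$empty_mad_pctl)
    flag_empty <- met$mad < q_mad &
      met$mad < policy$empty_mad_ratio * stats::median(met$mad)
    flag_blur <- Reduce(`|`, lapply(focus_channels, function(ch) {
      s <- met[[paste0("plls_", ch)]]
      s < stats::quantile(s, 1 - policy$blur_pctl) &
        s < stats::median(s) - policy$blur_slope_margin
    }))
    flag_debris <- Reduce(`|`, lapply(channels, function(ch) {
      v <- met[[paste0("otsu_", ch)]]
      v > stats::quantile(v, policy$debris_pctl) &
        v > policy$debris_otsu_ratio * stats::median(v) &
        v > policy$debris_otsu_min
    }))
  }
  met$flag_empty <- flag_empty
  met$flag_blurry <- flag_blur & !flag_empty
  met$flag_debris <- flag_debris
  met$flags <- apply(cbind(ifelse(met$flag_empty, "empty", ""),
                           ifelse(met$flag_blurry, "blurry", ""),
                           ifelse(met$flag_debris, "debris", "")), 1,
                     function(r) paste(r[nzchar(r)], collapse = ";"))
  met$accepted <- !nzchar(met$flags)
  met
}
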