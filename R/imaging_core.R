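# Core raster data model, thresholding primitives and file I/O shared by
# every pipeline stage.
#
# Conventions used throughout the package:
#   * rasters are base R numeric matrices, rows = y, columns = x;
#   * intensities are finite, non-negative, nominally on [0, 1];
#   * object connectivity is 8-connected, background 4-connected;
#   * a pixel is foreground iff its intensity is strictly greater than the
#     threshold;
#   * "standard deviation" always means the sample SD (n - 1 denominator).

#' Default pixel size at 20X magnification, in micrometers per pixel
#'
#' Derived from the instrument's printed pixel/length equivalences
#' (40 px = 13.0 um, 60 px = 19.5 um).
#' @export
GQ_PIXEL_SIZE_UM <- 0.325

#' Construct a multi-channel image tile
#'
#' A `ChannelStack` bundles the co-registered single-channel rasters of one
#' 20X field of view (typically DAPI, pTau, GFAP, IBA1 and CD74) together
#' with its pixel size and its offset in whole-slide coordinates.
#'
#' @param channels Named list of numeric matrices, all with identical
#'   dimensions; values must be finite and non-negative.
#' @param pixel_size_um Micrometers per pixel (default [GQ_PIXEL_SIZE_UM]).
#' @param tile_id Identifier for the tile.
#' @param origin_xy Length-2 numeric, tile offset (x, y) in whole-slide 20X
#'   pixel coordinates (0-based).
#' @return An object of class `ChannelStack`.
#' @export
channel_stack <- function(channels, pixel_size_um = GQ_PIXEL_SIZE_UM,
                          tile_id = "tile", origin_xy = c(0, 0)) {
  if (!is.list(channels) || length(channels) == 0L ||
      is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("'channels' must be a non-empty named list of matrices")
  dims <- lapply(channels, dim)
  if (any(vapply(dims, is.null, logical(1))))
    stop("all channels must be matrices")
  d1 <- dims[[1]]
  if (!all(vapply(dims, function(d) identical(d, d1), logical(1))))
    stop("all channel rasters must share identical dimensions")
  for (nm in names(channels)) {
    v <- channels[[nm]]
    if (!all(is.finite(v)))
      stop("channel '", nm, "' contains non-finite values")
    if (any(v < 0))
      stop("channel '", nm, "' contains negative intensities")
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("'pixel_size_um' must be a single positive number")
  structure(list(tile_id = as.character(tile_id),
                 channels = channels,
                 pixel_size_um = pixel_size_um,
                 origin_xy = as.numeric(origin_xy)),
            class = "ChannelStack")
}

#' @export
print.ChannelStack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("ChannelStack '%s': %d x %d px, %.3f um/px, channels: %s\n",
              x$tile_id, d[1], d[2], x$pixel_size_um,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Assert that a ChannelStack carries the required channels
#'
#' @param stack A [channel_stack()].
#' @param required Character vector of channel names the pipeline needs.
#' @return Invisibly `TRUE`; raises a configuration error otherwise.
#' @export
require_channels <- function(stack, required) {
  stopifnot(inherits(stack, "ChannelStack"))
  missing <- setdiff(required, names(stack$channels))
  if (length(missing))
    stop("configuration error: missing channel(s): ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Construct an integer label map for one object class
#'
#' Positive labels must be (or are relabeled to) the contiguous integers
#' `1..n_objects`; 0 is background.
#'
#' @param labels Integer matrix, values >= 0.
#' @param object_class One of `"nucleus"`, `"microglia_nucleus"`,
#'   `"microglia"`, `"microglia_fragment"`, `"astrocyte"`, `"ptau"`.
#' @param relabel Relabel positive values to contiguous 1..n (default TRUE).
#' @return An object of class `LabelMap`.
#' @export
label_map <- function(labels, object_class = "nucleus", relabel = TRUE) {
  classes <- c("nucleus", "microglia_nucleus", "microglia",
               "microglia_fragment", "astrocyte", "ptau")
  object_class <- match.arg(object_class, classes)
  if (is.null(dim(labels))) stop("'labels' must be a matrix")
  if (any(labels < 0)) stop("labels must be >= 0")
  lab <- labels
  storage.mode(lab) <- "integer"
  u <- sort(unique(lab[lab > 0L]))
  if (relabel && (length(u) == 0L || !identical(u, seq_along(u)))) {
    map <- integer(if (length(u)) max(u) else 0L)
    map[u] <- seq_along(u)
    pos <- lab > 0L
    lab[pos] <- map[lab[pos]]
    u <- seq_along(u)
  }
  structure(list(labels = lab,
                 n_objects = length(u),
                 object_class = object_class),
            class = "LabelMap")
}

#' @export
print.LabelMap <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("LabelMap (%s): %d x %d px, %d object(s)\n",
              x$object_class, d[1], d[2], x$n_objects))
  invisible(x)
}

#' Otsu threshold of an intensity raster
#'
#' Rescales intensities to \[0, 1\], bins them into `n_bins` histogram bins
#' and returns, on the original intensity scale, the bin edge that maximizes
#' the between-class variance. Pixels strictly greater than the threshold
#' are foreground. The lowest maximizing edge is returned on ties.
#'
#' @param img Numeric matrix (or vector) of intensities.
#' @param n_bins Number of histogram bins (default 256 regardless of bit
#'   depth, for reproducibility across acquisitions).
#' @return Scalar threshold on the scale of `img`.
#' @export
otsu_threshold <- function(img, n_bins = 256L) {
  v <- as.numeric(img)
  v <- v[is.finite(v)]
  if (length(v) < 2L) stop("degenerate input: need at least 2 pixels")
  lo <- min(v); hi <- max(v)
  if (hi == lo) stop("degenerate input: constant image has no Otsu threshold")
  z <- (v - lo) / (hi - lo)
  bin <- pmin(floor(z * n_bins) + 1L, n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  mids <- (seq_len(n_bins) - 0.5) / n_bins
  w <- cumsum(counts)                       # pixels in bins 1..k
  s <- cumsum(counts * mids)                # intensity mass in bins 1..k
  n <- w[n_bins]; stot <- s[n_bins]
  k <- seq_len(n_bins - 1L)                 # cut after bin k, edge k/n_bins
  w0 <- w[k]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, n_bins - 1L)
  m0 <- s[k][valid] / w0[valid]
  m1 <- (stot - s[k][valid]) / w1[valid]
  bcv[valid] <- (w0[valid] / n) * (w1[valid] / n) * (m0 - m1)^2
  kbest <- which.max(bcv)
  lo + (hi - lo) * kbest / n_bins
}

#' Robust background threshold (trimmed mean + k SD)
#'
#' Sorts pixel intensities, discards the lowest `lower_trim` and highest
#' `upper_trim` fractions, and returns the mean plus `sd_multiplier` sample
#' standard deviations of the retained pixels. This is the CellProfiler
#' "Robust Background" strategy used for nuclei, microglia fragments,
#' astrocytes (k = 2) and phospho-tau (k = 20).
#'
#' @param img Numeric matrix (or vector) of intensities.
#' @param lower_trim,upper_trim Fractions trimmed from each tail
#'   (defaults 0.05 / 0.05); their sum must be < 1.
#' @param sd_multiplier Non-negative multiplier k for the SD term.
#' @return Scalar threshold.
#' @export
robust_background_threshold <- function(img, lower_trim = 0.05,
                                        upper_trim = 0.05,
                                        sd_multiplier = 2) {
  stopifnot(lower_trim >= 0, upper_trim >= 0, sd_multiplier >= 0)
  if (lower_trim + upper_trim >= 1)
    stop("lower_trim + upper_trim must be < 1")
  v <- sort(as.numeric(img))
  n <- length(v)
  nlo <- floor(n * lower_trim)
  nhi <- floor(n * upper_trim)
  keep <- v[(nlo + 1L):(n - nhi)]
  if (length(keep) < 2L)
    stop("degenerate input: trimming leaves fewer than 2 pixels")
  mean(keep) + sd_multiplier * stats::sd(keep)
}

#' Convert between pixels and micrometers
#'
#' @param px,um Lengths in pixels / micrometers.
#' @param pixel_size_um Micrometers per pixel.
#' @return Converted length.
#' @export
px_to_um <- function(px, pixel_size_um = GQ_PIXEL_SIZE_UM) px * pixel_size_um

#' @rdname px_to_um
#' @export
um_to_px <- function(um, pixel_size_um = GQ_PIXEL_SIZE_UM) um / pixel_size_um

# ---- file I/O ----------------------------------------------------------

# 16-bit TIFF round trips: integer rasters in [0, 65535] are stored exactly.

#' Read a multi-channel tile from single-channel grayscale TIFF files
#'
#' @param path Directory containing one TIFF per channel.
#' @param channel_map Named character vector or list mapping channel name to
#'   file name (relative to `path`).
#' @param pixel_size_um Micrometers per pixel.
#' @param tile_id Tile identifier; defaults to the directory name.
#' @param origin_xy Tile offset in whole-slide 20X pixel coordinates.
#' @return A [channel_stack()]. Intensities are on \[0, 1\].
#' @export
read_tile <- function(path, channel_map,
                      pixel_size_um = GQ_PIXEL_SIZE_UM,
                      tile_id = basename(path), origin_xy = c(0, 0)) {
  if (is.null(names(channel_map)) || any(!nzchar(names(channel_map))))
    stop("configuration error: 'channel_map' must be named by channel")
  channels <- lapply(names(channel_map), function(ch) {
    f <- file.path(path, channel_map[[ch]])
    if (!file.exists(f))
      stop("configuration error: file for channel '", ch,
           "' not found: ", f)
    m <- tiff::readTIFF(f)
    if (length(dim(m)) == 3L) m <- m[, , 1]   # tolerate single-plane RGB
    m
  })
  names(channels) <- names(channel_map)
  channel_stack(channels, pixel_size_um = pixel_size_um,
                tile_id = tile_id, origin_xy = origin_xy)
}

#' Write a multi-channel tile as one 16-bit grayscale TIFF per channel
#'
#' Intensities are clamped to \[0, 1\] and quantized to 16 bits; data
#' already on the 16-bit grid round-trip losslessly.
#'
#' @param stack A [channel_stack()].
#' @param path Output directory (created if needed).
#' @param channel_map Optional named map channel -> file name; defaults to
#'   `<CHANNEL>.tif`.
#' @return Invisibly, the named vector of written file paths.
#' @export
write_tile <- function(stack, path, channel_map = NULL) {
  stopifnot(inherits(stack, "ChannelStack"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (is.null(channel_map))
    channel_map <- stats::setNames(paste0(names(stack$channels), ".tif"),
                                   names(stack$channels))
  out <- character(0)
  for (ch in names(stack$channels)) {
    f <- file.path(path, channel_map[[ch]])
    m <- pmin(pmax(stack$channels[[ch]], 0), 1)
    tiff::writeTIFF(round(m * 65535) / 65535, f, bits.per.sample = 16L)
    out[ch] <- f
  }
  invisible(out)
}

#' Write / read a label map as a 16-bit TIFF
#'
#' Labels up to 65535 are stored exactly; `read_labelmap(write_labelmap(x))`
#' reproduces the raster.
#'
#' @param labelmap A [label_map()].
#' @param path Output TIFF file.
#' @return `write_labelmap` invisibly returns `path`; `read_labelmap`
#'   returns a [label_map()].
#' @export
write_labelmap <- function(labelmap, path) {
  stopifnot(inherits(labelmap, "LabelMap"))
  if (labelmap$n_objects > 65535L)
    stop("more than 65535 objects cannot be stored in a 16-bit TIFF")
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  tiff::writeTIFF(labelmap$labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_labelmap
#' @param object_class Object class to stamp on the map read back.
#' @export
read_labelmap <- function(path, object_class = "nucleus") {
  m <- tiff::readTIFF(path)
  label_map(round(m * 65535), object_class = object_class, relabel = FALSE)
}

#' Write / read a per-object feature table as CSV
#'
#' Fixed schema: `tile_id, label, class, centroid_x, centroid_y, area_px,
#' perimeter_px, equiv_diam_px, compactness, eccentricity,
#' mean_<CHANNEL>..., flags`. An empty table yields a header-only CSV.
#' `flags` is a semicolon-joined tag string.
#'
#' @param objects Data frame of object records (see [measure_objects()]).
#' @param path Output CSV file.
#' @return `write_object_table` invisibly returns `path`;
#'   `read_object_table` returns the data frame.
#' @export
write_object_table <- function(objects, path) {
  base_cols <- c("tile_id", "label", "class", "centroid_x", "centroid_y",
                 "area_px", "perimeter_px", "equiv_diam_px", "compactness",
                 "eccentricity")
  if (is.null(objects) || nrow(objects) == 0L) {
    objects <- as.data.frame(stats::setNames(
      rep(list(logical(0)), length(base_cols) + 1L),
      c(base_cols, "flags")))
  } else {
    mean_cols <- grep("^mean_", names(objects), value = TRUE)
    if (!"flags" %in% names(objects)) objects$flags <- ""
    missing <- setdiff(base_cols, names(objects))
    if (length(missing))
      stop("object table lacks column(s): ", paste(missing, collapse = ", "))
    objects <- objects[, c(base_cols, mean_cols, "flags")]
  }
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(objects, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_object_table
#' @export
read_object_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(flags = "character"))
}
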