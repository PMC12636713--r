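# Tissue and gray-matter delineation from the low-magnification (4X)
# brightfield + DAPI whole-slide pair, and gray-matter gating of 20X tiles.

#' Default pixel size of the 4X overview, in micrometers per pixel
#' @export
GQ_PIXEL_SIZE_4X_UM <- GQ_PIXEL_SIZE_UM * 5

#' Detect tissue from a 4X brightfield + DAPI pair
#'
#' Each channel is Otsu-binarized separately: tissue absorbs light, so the
#' brightfield foreground is the *below*-threshold class (configurable via
#' `brightfield_dark_is_tissue`), while the DAPI foreground is the
#' above-threshold class. The tissue mask is the pixel-wise intersection,
#' hole-filled, with connected components smaller than `min_area_mm2`
#' removed (dust and debris specks).
#'
#' @param brightfield,dapi Numeric matrices of identical dimensions.
#' @param min_area_mm2 Minimum component area retained (default 0.1 mm^2).
#' @param pixel_size_um 4X pixel size in micrometers.
#' @param brightfield_dark_is_tissue If `TRUE` (default), tissue is the
#'   dark brightfield class.
#' @return Logical matrix (tissue mask). An empty intersection yields an
#'   all-`FALSE` mask with a warning, not an error.
#' @export
detect_tissue <- function(brightfield, dapi, min_area_mm2 = 0.1,
                          pixel_size_um = GQ_PIXEL_SIZE_4X_UM,
                          brightfield_dark_is_tissue = TRUE) {
  if (!identical(dim(brightfield), dim(dapi)))
    stop("brightfield and DAPI rasters must share dimensions")
  t_bf <- otsu_threshold(brightfield)
  t_dapi <- otsu_threshold(dapi)
  bf_fg <- if (brightfield_dark_is_tissue) brightfield <= t_bf
           else brightfield > t_bf
  mask <- bf_fg & (dapi > t_dapi)
  if (!any(mask)) {
    warning("empty tissue mask: brightfield and DAPI foregrounds do not intersect")
    return(mask)
  }
  filled <- EBImage::fillHull(mask * 1) > 0
  lab <- label8(filled)
  min_px <- min_area_mm2 * 1e6 / pixel_size_um^2
  if (max(lab) > 0L) {
    areas <- tabulate(lab[lab > 0L])
    drop <- which(areas < min_px)
    if (length(drop)) filled[lab %in% drop] <- FALSE
  }
  if (!any(filled))
    warning("empty tissue mask after minimum-area filtering")
  filled
}

#' Segment gray matter within detected tissue
#'
#' A second Otsu threshold is computed on the brightfield intensities
#' restricted to tissue pixels; the darker class (denser, more absorbing
#' cortex) is labeled gray matter (2), the brighter class white matter (1).
#'
#' @param brightfield 4X brightfield raster.
#' @param tissue_mask Logical tissue mask from [detect_tissue()].
#' @param scale_to_tile Linear factor from 4X to 20X pixel coordinates
#'   (default 5, the nominal magnification ratio).
#' @param pixel_size_um 4X pixel size in micrometers.
#' @return A `TissueMask`: list with `labels` (0 background / 1 white /
#'   2 gray), `scale_to_tile` and `pixel_size_um`.
#' @export
segment_gray_matter <- function(brightfield, tissue_mask,
                                scale_to_tile = 5,
                                pixel_size_um = GQ_PIXEL_SIZE_4X_UM) {
  if (!identical(dim(brightfield), dim(tissue_mask)))
    stop("brightfield and tissue mask must share dimensions")
  if (!any(tissue_mask)) stop("tissue mask is empty")
  vals <- brightfield[tissue_mask]
  if (length(unique(vals)) < 2L)
    stop("degenerate input: tissue has fewer than 2 distinct intensities")
  t_gw <- otsu_threshold(vals)
  labels <- matrix(0L, nrow(brightfield), ncol(brightfield))
  labels[tissue_mask & brightfield > t_gw] <- 1L   # brighter: white matter
  labels[tissue_mask & brightfield <= t_gw] <- 2L  # darker: gray matter
  structure(list(labels = labels, scale_to_tile = scale_to_tile,
                 pixel_size_um = pixel_size_um),
            class = "TissueMask")
}

#' @export
print.TissueMask <- function(x, ...) {
  cat(sprintf(
    "TissueMask: %d x %d px (4X), gray %.3f mm^2, white %.3f mm^2\n",
    nrow(x$labels), ncol(x$labels),
    gray_area_mm2(x), tissue_class_area_mm2(x, 1L)))
  invisible(x)
}

tissue_class_area_mm2 <- function(mask, class_label) {
  sum(mask$labels == class_label) * mask$pixel_size_um^2 / 1e6
}

#' Gray-matter area of a tissue mask in mm^2
#' @param mask A `TissueMask`.
#' @export
gray_area_mm2 <- function(mask) tissue_class_area_mm2(mask, 2L)

#' Gray-matter fraction of a 20X tile footprint
#'
#' Maps the tile footprint into the 4X grid (nearest-neighbor: the set of
#' 4X pixels covered by the tile) and returns the fraction of covered 4X
#' pixels labeled gray matter. A tile is accepted only if *more than*
#' `cutoff` (default 0.95) of its footprint is gray matter; a fraction of
#' exactly 0.95 is rejected.
#'
#' @param mask A `TissueMask`.
#' @param tile_origin_xy Tile offset (x, y) in whole-slide 20X pixel
#'   coordinates (0-based).
#' @param tile_shape Tile size `c(width, height)` in 20X pixels.
#' @param cutoff Strict acceptance cutoff on the gray fraction.
#' @return List with `fraction` and `accepted`.
#' @export
tile_gray_fraction <- function(mask, tile_origin_xy, tile_shape,
                               cutoff = 0.95) {
  stopifnot(inherits(mask, "TissueMask"))
  s <- mask$scale_to_tile
  x0 <- tile_origin_xy[1]; y0 <- tile_origin_xy[2]
  w <- tile_shape[1]; h <- tile_shape[2]
  cols4 <- unique(floor((x0 + seq_len(w) - 1) / s)) + 1L
  rows4 <- unique(floor((y0 + seq_len(h) - 1) / s)) + 1L
  if (min(rows4) < 1L || min(cols4) < 1L ||
      max(rows4) > nrow(mask$labels) || max(cols4) > ncol(mask$labels))
    stop("coordinate error: tile footprint outside the 4X mask bounds")
  fraction <- mean(mask$labels[rows4, cols4] == 2L)
  list(fraction = fraction, accepted = fraction > cutoff)
}

#' Gray-matter area covered by a set of accepted tiles, in mm^2
#'
#' Sums gray-labeled 4X pixels over the tile footprints; used as the
#' denominator of per-mm^2 densities.
#'
#' @param mask A `TissueMask`.
#' @param tile_origins List (or n x 2 matrix) of tile origins in 20X pixel
#'   coordinates.
#' @param tile_shape Tile size `c(width, height)` in 20X pixels.
#' @return Scalar area in mm^2.
#' @export
tiles_gray_area_mm2 <- function(mask, tile_origins, tile_shape) {
  if (is.matrix(tile_origins))
    tile_origins <- split(tile_origins, seq_len(nrow(tile_origins)))
  s <- mask$scale_to_tile
  total_px <- 0
  for (o in tile_origins) {
    cols4 <- unique(floor((o[1] + seq_len(tile_shape[1]) - 1) / s)) + 1L
    rows4 <- unique(floor((o[2] + seq_len(tile_shape[2]) - 1) / s)) + 1L
    total_px <- total_px + sum(mask$labels[rows4, cols4] == 2L)
  }
  total_px * mask$pixel_size_um^2 / 1e6
}
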