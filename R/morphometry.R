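# Per-object shape and intensity features.
#
# Coordinate convention: pixel centers at integer (row, col) positions;
# centroids are intensity-unweighted. Reported centroid_x = column,
# centroid_y = row.

#' Compactness of a pixel set
#'
#' Compactness is the mean squared distance (MSD) of an object's pixels from
#' its (unweighted) centroid divided by its area, normalized so that a
#' filled circle scores 1:
#' \deqn{C = 2\pi \cdot MSD / A.}
#' The 2*pi factor is required by the circle anchor: for a disk of radius R,
#' MSD = R^2/2 and A = pi R^2, so the raw ratio MSD/A is 1/(2*pi).
#' Ramified or branched objects score above 1; a single pixel scores 0.
#'
#' @param rows,cols Integer vectors of pixel coordinates (pixel centers).
#' @return Scalar compactness >= 0.
#' @export
compactness <- function(rows, cols) {
  stopifnot(length(rows) == length(cols), length(rows) >= 1L)
  a <- length(rows)
  msd <- mean((rows - mean(rows))^2 + (cols - mean(cols))^2)
  2 * pi * msd / a
}

#' Eccentricity of the best-fit ellipse of a pixel set
#'
#' Computed from the second central moments; 0 for a disk, approaching 1
#' for elongated objects.
#'
#' @inheritParams compactness
#' @return Eccentricity in \[0, 1).
#' @export
eccentricity <- function(rows, cols) {
  stopifnot(length(rows) == length(cols), length(rows) >= 1L)
  m20 <- mean((cols - mean(cols))^2)
  m02 <- mean((rows - mean(rows))^2)
  m11 <- mean((cols - mean(cols)) * (rows - mean(rows)))
  d <- sqrt(((m20 - m02) / 2)^2 + m11^2)
  l1 <- (m20 + m02) / 2 + d
  l2 <- (m20 + m02) / 2 - d
  if (l1 <= 0) return(0)
  sqrt(max(0, 1 - l2 / l1))
}

#' Equivalent diameter: diameter of the circle with the object's area
#'
#' @param area_px Pixel count.
#' @return Diameter in pixels, `2 * sqrt(area / pi)`.
#' @export
equivalent_diameter <- function(area_px) 2 * sqrt(area_px / pi)

# Perimeter by boundary-step weighting (local-configuration estimator):
# boundary pixels are foreground pixels 4-adjacent to background; each is
# weighted by its local boundary configuration so straight runs count 1,
# diagonal steps sqrt(2) and corner pixels (1 + sqrt(2))/2. This is the
# classical weighted estimator also used by scikit-image.
perimeter_mask <- function(mask) {
  stopifnot(is.matrix(mask))
  if (!any(mask)) return(0)
  m <- mask * 1
  pad <- matrix(0, nrow(m) + 2L, ncol(m) + 2L)
  pad[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
  i <- 2:(nrow(m) + 1L); j <- 2:(ncol(m) + 1L)
  eroded <- pad[i, j] * pad[i - 1L, j] * pad[i + 1L, j] *
    pad[i, j - 1L] * pad[i, j + 1L]
  border <- pad[i, j] - eroded
  bp <- matrix(0, nrow(m) + 2L, ncol(m) + 2L)
  bp[i, j] <- border
  conv <- 1 * bp[i, j] +
    2 * (bp[i - 1L, j] + bp[i + 1L, j] + bp[i, j - 1L] + bp[i, j + 1L]) +
    10 * (bp[i - 1L, j - 1L] + bp[i - 1L, j + 1L] +
            bp[i + 1L, j - 1L] + bp[i + 1L, j + 1L])
  w <- numeric(50)                       # w[v + 1] = weight of config value v
  w[c(5, 7, 15, 17, 25, 27) + 1L] <- 1
  w[c(21, 33) + 1L] <- sqrt(2)
  w[c(13, 23) + 1L] <- (1 + sqrt(2)) / 2
  vals <- round(conv[border > 0])
  sum(w[pmin(vals, 49L) + 1L])
}

#' Perimeter of an object's pixel set
#'
#' Boundary-step-weighted perimeter estimate (see `perimeter_mask`); for a
#' rasterized disk of radius R it approximates 2*pi*R.
#'
#' @inheritParams compactness
#' @return Perimeter in pixels.
#' @export
perimeter <- function(rows, cols) {
  stopifnot(length(rows) == length(cols), length(rows) >= 1L)
  r0 <- min(rows); c0 <- min(cols)
  mask <- matrix(FALSE, max(rows) - r0 + 1L, max(cols) - c0 + 1L)
  mask[cbind(rows - r0 + 1L, cols - c0 + 1L)] <- TRUE
  perimeter_mask(mask)
}

#' Mean per-channel intensity within an object
#'
#' @param rows,cols Pixel coordinates of the object.
#' @param stack A [channel_stack()].
#' @param channels Channels to measure (default all in `stack`).
#' @return Named numeric vector of arithmetic mean intensities.
#' @export
measure_intensity <- function(rows, cols, stack, channels = NULL) {
  stopifnot(inherits(stack, "ChannelStack"))
  if (is.null(channels)) channels <- names(stack$channels)
  require_channels(stack, channels)
  idx <- cbind(rows, cols)
  vapply(channels, function(ch) mean(stack$channels[[ch]][idx]), numeric(1))
}

#' Measure all objects of a label map
#'
#' Produces one `ObjectRecord` row per labeled object: centroid, area,
#' perimeter, equivalent diameter, compactness, eccentricity and (when a
#' `ChannelStack` is supplied) per-channel mean intensities as
#' `mean_<CHANNEL>` columns.
#'
#' @param labelmap A [label_map()].
#' @param stack Optional [channel_stack()] for intensity measurement.
#' @param tile_id Tile identifier stamped on each row; defaults to the
#'   stack's id or `"tile"`.
#' @param channels Channels to measure (default all).
#' @return Data frame with one row per object (possibly 0 rows).
#' @export
measure_objects <- function(labelmap, stack = NULL, tile_id = NULL,
                            channels = NULL) {
  stopifnot(inherits(labelmap, "LabelMap"))
  if (is.null(tile_id))
    tile_id <- if (!is.null(stack)) stack$tile_id else "tile"
  lab <- labelmap$labels
  n <- labelmap$n_objects
  empty <- data.frame(tile_id = character(0), label = integer(0),
                      class = character(0), centroid_x = numeric(0),
                      centroid_y = numeric(0), area_px = numeric(0),
                      perimeter_px = numeric(0), equiv_diam_px = numeric(0),
                      compactness = numeric(0), eccentricity = numeric(0),
                      flags = character(0), stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  idx <- which(lab > 0L)
  l <- lab[idx]
  rr <- ((idx - 1L) %% nrow(lab)) + 1L
  cc <- ((idx - 1L) %/% nrow(lab)) + 1L
  ord <- order(l)
  l <- l[ord]; rr <- rr[ord]; cc <- cc[ord]
  bounds <- c(0L, cumsum(tabulate(l, nbins = n)))
  rec <- vector("list", n)
  for (k in seq_len(n)) {
    sel <- (bounds[k] + 1L):bounds[k + 1L]
    r <- rr[sel]; cl <- cc[sel]
    row <- data.frame(tile_id = tile_id, label = k,
                      class = labelmap$object_class,
                      centroid_x = mean(cl), centroid_y = mean(r),
                      area_px = length(r),
                      perimeter_px = perimeter(r, cl),
                      equiv_diam_px = equivalent_diameter(length(r)),
                      compactness = compactness(r, cl),
                      eccentricity = eccentricity(r, cl),
                      stringsAsFactors = FALSE)
    if (!is.null(stack)) {
      mi <- measure_intensity(r, cl, stack, channels)
      for (ch in names(mi)) row[[paste0("mean_", ch)]] <- mi[[ch]]
    }
    row$flags <- ""
    rec[[k]] <- row
  }
  do.call(rbind, rec)
}
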