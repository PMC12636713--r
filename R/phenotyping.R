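# Statistical classification of segmented cells and per-section
# aggregation.

#' Flag marker-high objects (mean + k SD rule)
#'
#' An object is marker-high when its mean fluorescence intensity is
#' strictly greater than the mean plus `sd_multiplier` sample standard
#' deviations of the intensities of *all* objects in the same donor
#' section (never pooled across donors). Used to define CD74-high
#' microglia. The rule is invariant to affine intensity rescaling
#' `I -> a*I + b` (a > 0).
#'
#' @param intensity Numeric vector of per-object mean intensities for one
#'   donor section (>= 3 values).
#' @param sd_multiplier k in mean + k SD (default 2).
#' @return Logical vector of flags, with the threshold attached as
#'   attribute `"threshold"`.
#' @export
classify_marker_high <- function(intensity, sd_multiplier = 2) {
  if (length(intensity) < 3L)
    stop("insufficient population: need at least 3 objects")
  threshold <- mean(intensity) + sd_multiplier * stats::sd(intensity)
  structure(intensity > threshold, threshold = threshold)
}

#' Flag morphologically rounded cells
#'
#' Rounded means compactness less than or equal to `cutoff` (default 2.5;
#' the boundary value itself counts as rounded). An operational proxy for
#' morphologically activated, amoeboid (stage III) microglia.
#'
#' @param compactness Numeric vector of per-object compactness values.
#' @param cutoff Inclusive upper bound (default 2.5).
#' @return Logical vector.
#' @export
classify_rounded <- function(compactness, cutoff = 2.5) {
  compactness <= cutoff
}

#' Aggregate per-object results into a per-donor section summary
#'
#' Computes gray-matter-normalized densities, the CD74-high and rounded
#' percentages (including rounded percentages within the CD74-high and
#' CD74-low subsets, which partition the microglia), and the phospho-tau
#' burden. Only objects from QC-accepted, gray-gated tiles should be
#' passed in. Percentage fields are `NA` (missing, not 0) when their
#' denominator is 0.
#'
#' @param microglia Feature table of microglia objects (needs
#'   `compactness` and `mean_<marker>`); may have 0 rows.
#' @param astrocytes Feature table of astrocyte objects (may be `NULL`).
#' @param ptau Result of [classify_ptau()] (may be `NULL`).
#' @param gray_area_mm2 Gray-matter area of the accepted tiles in mm^2
#'   (> 0).
#' @param donor_id Donor identifier.
#' @param n_tiles_accepted Number of contributing tiles.
#' @param marker Channel used for the marker-high split (default
#'   `"CD74"`).
#' @param sd_multiplier,rounded_cutoff Classifier parameters.
#' @return One-row data frame (`SectionSummary`).
#' @export
aggregate_section <- function(microglia, astrocytes = NULL, ptau = NULL,
                              gray_area_mm2, donor_id = "donor",
                              n_tiles_accepted = NA_integer_,
                              marker = "CD74", sd_multiplier = 2,
                              rounded_cutoff = 2.5) {
  if (!is.numeric(gray_area_mm2) || gray_area_mm2 <= 0)
    stop("undefined density: gray-matter area must be positive")
  n_mg <- if (is.null(microglia)) 0L else nrow(microglia)
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  if (n_mg >= 3L) {
    mcol <- paste0("mean_", marker)
    if (!mcol %in% names(microglia))
      stop("configuration error: microglia table lacks ", mcol)
    high <- classify_marker_high(microglia[[mcol]], sd_multiplier)
    rounded <- classify_rounded(microglia$compactness, rounded_cutoff)
    pct_high <- pct(sum(high), n_mg)
    pct_round <- pct(sum(rounded), n_mg)
    pct_round_high <- pct(sum(rounded & high), sum(high))
    pct_round_low <- pct(sum(rounded & !high), sum(!high))
  } else {
    pct_high <- pct_round <- pct_round_high <- pct_round_low <- NA_real_
  }
  n_ast <- if (is.null(astrocytes)) 0L else nrow(astrocytes)
  data.frame(
    donor_id = donor_id,
    n_tiles_accepted = n_tiles_accepted,
    gray_area_mm2 = gray_area_mm2,
    n_microglia = n_mg,
    microglia_density_per_mm2 = n_mg / gray_area_mm2,
    pct_cd74_high = pct_high,
    pct_rounded = pct_round,
    pct_rounded_in_cd74_high = pct_round_high,
    pct_rounded_in_cd74_low = pct_round_low,
    n_astrocytes = n_ast,
    astrocyte_density_per_mm2 = n_ast / gray_area_mm2,
    ptau_area_occupied_mm2 = if (is.null(ptau)) 0 else ptau$area_occupied_mm2,
    ptau_thread_count = if (is.null(ptau)) 0L else unname(ptau$counts["threads"]),
    ptau_tangle_count = if (is.null(ptau)) 0L else unname(ptau$counts["tangles"]),
    stringsAsFactors = FALSE)
}
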