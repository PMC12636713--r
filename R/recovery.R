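# Ground-truth recovery evaluation: run the pipeline on a generated
# section and score it against the generator's ground truth. Used for
# validation (tests, reproduction script) and as a worked example of the
# full stack.

#' Run the pipeline on a synthetic section and score it against truth
#'
#' Generates a section, delineates gray matter from the 4X pair, gates
#' tiles at the 95% gray cutoff, quality-controls them, segments microglia
#' on the accepted tiles (with the IBA1 nucleus gate pooled over the
#' section), and compares the result with the generator's ground truth:
#' microglial density per mm^2, the CD74-high percentage, and per-cell
#' recall/precision (a detected cell matches a true cell when its nucleus
#' centroid lies within `match_radius_px`).
#'
#' @param seed Integer seed for the section.
#' @param section_params [sim_section_params()].
#' @param seg [seg_params()].
#' @param match_radius_px Centroid matching radius (default 10 px).
#' @param marker Marker channel for the high/low split (default CD74).
#' @return List: `truth_density`, `est_density`, `truth_pct_high`,
#'   `est_pct_high`, `n_truth`, `n_detected`, `n_matched`, `recall`,
#'   `precision`, `gray_area_mm2`, and the per-object `microglia` table.
#' @export
evaluate_recovery <- function(seed, section_params = sim_section_params(),
                              seg = seg_params(), match_radius_px = 10,
                              marker = "CD74") {
  sec <- generate_section(section_params, seed = seed)
  tissue <- detect_tissue(sec$brightfield_4x, sec$dapi_4x)
  mask <- segment_gray_matter(sec$brightfield_4x, tissue)
  shape <- rep(sec$truth$tile_px, 2)
  gate <- vapply(seq_along(sec$tiles), function(k)
    tile_gray_fraction(mask, sec$truth$tile_origins[k, ], shape)$accepted,
    logical(1))
  qc <- suppressWarnings(qc_tiles(sec$tiles[gate]))
  acc_idx <- which(gate)[qc$accepted]
  tiles <- sec$tiles[acc_idx]
  garea <- tiles_gray_area_mm2(mask,
                               lapply(acc_idx, function(k)
                                 sec$truth$tile_origins[k, ]), shape)
  # pooled IBA1 gate population over the section's accepted tiles
  nuc_maps <- lapply(tiles, function(tl)
    identify_primary_objects(tl$channels$DAPI, seg$nucleus_diam_px,
                             "robust_background", "shape",
                             threshold_args = list(
                               lower_trim = seg$robust_trim[1],
                               upper_trim = seg$robust_trim[2])))
  pop <- unlist(lapply(seq_along(tiles), function(i)
    measure_objects(nuc_maps[[i]], tiles[[i]])$mean_IBA1))
  n_matched <- 0L; n_det <- 0L; n_truth <- 0L
  mg_tabs <- list()
  cells <- sec$truth$cells
  for (i in seq_along(tiles)) {
    tl <- tiles[[i]]
    sel <- tryCatch(
      select_microglia_nuclei(nuc_maps[[i]], tl$channels$IBA1,
                              seg$microglia_nucleus_max_equiv_diam_px,
                              seg$iba1_sd_multiplier, population_iba1 = pop),
      error = function(e) NULL)
    if (is.null(sel)) next
    tub <- enhance_tubeness(tl$channels$IBA1, seg$tubeness_scale_microglia)
    frag <- identify_primary_objects(
      tub, seg$fragment_diam_px, "robust_background", "intensity",
      threshold_args = list(lower_trim = seg$robust_trim[1],
                            upper_trim = seg$robust_trim[2]),
      object_class = "microglia_fragment")
    mg <- assemble_microglia(frag, sel$labels, seg$fragment_link_radius_px,
                             tl, tl$tile_id)
    mg_tabs[[length(mg_tabs) + 1L]] <- mg$objects
    nuctab <- measure_objects(sel$labels)
    truth_i <- cells[cells$class == "microglia" &
                       cells$tile_index == acc_idx[i], , drop = FALSE]
    n_truth <- n_truth + nrow(truth_i)
    n_det <- n_det + nrow(nuctab)
    if (nrow(nuctab) && nrow(truth_i)) {
      d <- sqrt(outer(nuctab$centroid_y, truth_i$y, "-")^2 +
                  outer(nuctab$centroid_x, truth_i$x, "-")^2)
      n_matched <- n_matched + sum(apply(d, 2, min) < match_radius_px)
    }
  }
  microglia <- if (length(mg_tabs)) do.call(rbind, mg_tabs) else NULL
  est_pct <- NA_real_
  if (!is.null(microglia) && nrow(microglia) >= 3L)
    est_pct <- 100 * mean(classify_marker_high(
      microglia[[paste0("mean_", marker)]]))
  truth_mg <- cells[cells$class == "microglia" &
                      cells$tile_index %in% acc_idx, , drop = FALSE]
  list(truth_density = nrow(truth_mg) / garea,
       est_density = n_det / garea,
       truth_pct_high = if (nrow(truth_mg)) 100 * mean(truth_mg$cd74_high)
                        else NA_real_,
       est_pct_high = est_pct,
       n_truth = nrow(truth_mg), n_detected = n_det,
       n_matched = n_matched,
       recall = if (n_truth) n_matched / n_truth else NA_real_,
       precision = if (n_det) n_matched / n_det else NA_real_,
       gray_area_mm2 = garea,
       microglia = microglia)
}
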