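# Pipeline orchestration: simulate -> detect-tissue -> qc -> segment ->
# quantify -> associate, as one reproducible run with config, manifest
# and plain directory-tree outputs.

#' Default run configuration
#'
#' Fully serializable (YAML); written verbatim into the output directory
#' of every run for provenance.
#'
#' @param ... Named overrides of the defaults.
#' @return List of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    donor_id = "donor",
    channels = c("DAPI", "AT8", "GFAP", "IBA1", "CD74"),
    pixel_size_um = GQ_PIXEL_SIZE_UM,
    gray_fraction_cutoff = 0.95,
    segment_astrocytes = TRUE,
    pool_iba1_gate = TRUE,
    seg = list(),            # seg_params() overrides
    qc = list(),             # qc_policy() overrides
    simulate = list(),       # sim_section_params() overrides
    traits = NULL            # optional path to a donor trait CSV
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("validation error: unknown config field(s): ",
         paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  required <- c("DAPI", "IBA1", "AT8")
  missing <- setdiff(required, cfg$channels)
  if (length(missing))
    stop("validation error: config lacks required channel(s): ",
         paste(missing, collapse = ", "))
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as YAML
#' @param path YAML file path.
#' @param cfg A [run_config()].
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Run the full pipeline on a synthetic section
#'
#' Executes every stage on a generated section and writes a plain
#' directory tree: the verbatim config, the 4X pair and tiles (16-bit
#' TIFFs), the tissue mask + JSON sidecar, the QC report, per-tile object
#' tables, the section summary and a manifest with per-stage counts and
#' the config hash. Rerunning with the same config and seed reproduces
#' the CSVs byte for byte. Stage failures abort downstream stages and are
#' recorded in the manifest.
#'
#' @param cfg A [run_config()].
#' @param out_dir Output directory.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(out_dir, "config.yaml")
  write_run_config(cfg, cfg_path)
  manifest <- list(package_version = as.character(utils::packageVersion("gliaquant")),
                   config_hash = unname(tools::md5sum(cfg_path)),
                   seed = cfg$seed, stages = list())
  t_all <- Sys.time()

  # -- simulate ----------------------------------------------------------
  sec <- generate_section(do.call(sim_section_params, cfg$simulate),
                          seed = cfg$seed)
  sim_dir <- file.path(out_dir, "sim")
  dir.create(sim_dir, showWarnings = FALSE)
  tiff::writeTIFF(round(pmin(pmax(sec$brightfield_4x, 0), 1) * 65535) / 65535,
                  file.path(sim_dir, "brightfield_4x.tif"),
                  bits.per.sample = 16L)
  tiff::writeTIFF(round(pmin(pmax(sec$dapi_4x, 0), 1) * 65535) / 65535,
                  file.path(sim_dir, "dapi_4x.tif"), bits.per.sample = 16L)
  manifest$stages$simulate <- list(n_tiles = length(sec$tiles))

  # -- tissue detection --------------------------------------------------
  tissue <- detect_tissue(sec$brightfield_4x, sec$dapi_4x)
  mask <- segment_gray_matter(sec$brightfield_4x, tissue)
  mask_dir <- file.path(out_dir, "tissue")
  dir.create(mask_dir, showWarnings = FALSE)
  tiff::writeTIFF(mask$labels / 255, file.path(mask_dir, "tissue_mask.tif"),
                  bits.per.sample = 8L)
  jsonlite::write_json(
    list(scale_to_tile = mask$scale_to_tile,
         pixel_size_um = mask$pixel_size_um,
         gray_area_mm2 = gray_area_mm2(mask),
         white_area_mm2 = tissue_class_area_mm2(mask, 1L)),
    file.path(mask_dir, "tissue_mask.json"), auto_unbox = TRUE, digits = NA)
  tile_shape <- rep(dim(sec$tiles[[1]]$channels[[1]])[1], 2)
  gate <- lapply(sec$tiles, function(tl)
    tile_gray_fraction(mask, tl$origin_xy, tile_shape,
                       cutoff = cfg$gray_fraction_cutoff))
  gray_ok <- vapply(gate, `[[`, logical(1), "accepted")
  manifest$stages$tissue <- list(gray_area_mm2 = gray_area_mm2(mask),
                                 n_tiles_gray = sum(gray_ok))

  # -- qc ----------------------------------------------------------------
  qc <- suppressWarnings(
    qc_tiles(sec$tiles[gray_ok], do.call(qc_policy, cfg$qc)))
  utils::write.csv(qc, file.path(out_dir, "qc_report.csv"),
                   row.names = FALSE)
  keep_ids <- qc$tile_id[qc$accepted]
  accepted <- sec$tiles[gray_ok][qc$accepted]
  manifest$stages$qc <- list(n_in = nrow(qc), n_accepted = length(accepted))

  # -- segmentation ------------------------------------------------------
  seg_dir <- file.path(out_dir, "objects")
  dir.create(seg_dir, showWarnings = FALSE)
  params <- do.call(seg_params, cfg$seg)
  pop_iba1 <- NULL
  results <- vector("list", length(accepted))
  if (isTRUE(cfg$pool_iba1_gate) && length(accepted)) {
    # first pass: pooled per-nucleus IBA1 means over all accepted tiles
    pop_iba1 <- unlist(lapply(accepted, function(tl) {
      nuc <- identify_primary_objects(
        tl$channels$DAPI, params$nucleus_diam_px, "robust_background",
        "shape", threshold_args = list(lower_trim = params$robust_trim[1],
                                       upper_trim = params$robust_trim[2]))
      measure_objects(nuc, tl)$mean_IBA1
    }))
  }
  mg_tabs <- list(); ast_tabs <- list(); pt_tabs <- list()
  for (i in seq_along(accepted)) {
    tl <- accepted[[i]]
    res <- segment_tile(tl, params, population_iba1 = pop_iba1,
                        astrocytes = isTRUE(cfg$segment_astrocytes) &&
                          "GFAP" %in% names(tl$channels))
    if (!is.null(res$microglia)) {
      tab <- res$microglia$objects
      if (nrow(tab)) {
        tab$centroid_x <- tab$centroid_x + tl$origin_xy[1]  # whole-slide X/Y
        tab$centroid_y <- tab$centroid_y + tl$origin_xy[2]
        mg_tabs[[length(mg_tabs) + 1L]] <- tab
      }
      write_labelmap(res$microglia$labels,
                     file.path(seg_dir, paste0(tl$tile_id, "_microglia.tif")))
    }
    if (!is.null(res$astrocytes) && nrow(res$astrocytes$objects))
      ast_tabs[[length(ast_tabs) + 1L]] <- res$astrocytes$objects
    if (nrow(res$ptau$objects))
      pt_tabs[[length(pt_tabs) + 1L]] <- res$ptau$objects
    results[[i]] <- res
  }
  bind <- function(l) if (length(l)) do.call(rbind, l) else NULL
  microglia <- bind(mg_tabs); astro <- bind(ast_tabs); ptau_obj <- bind(pt_tabs)
  write_object_table(microglia, file.path(seg_dir, "microglia.csv"))
  write_object_table(astro, file.path(seg_dir, "astrocytes.csv"))
  write_object_table(ptau_obj, file.path(seg_dir, "ptau.csv"))
  manifest$stages$segment <- list(
    n_microglia = if (is.null(microglia)) 0L else nrow(microglia),
    n_astrocytes = if (is.null(astro)) 0L else nrow(astro),
    n_ptau = if (is.null(ptau_obj)) 0L else nrow(ptau_obj))

  # -- quantify ----------------------------------------------------------
  acc_origins <- lapply(sec$tiles[gray_ok][qc$accepted], `[[`, "origin_xy")
  garea <- tiles_gray_area_mm2(mask, acc_origins, tile_shape)
  ptcls <- classify_ptau(if (is.null(ptau_obj)) data.frame(area_px = numeric(0))
                         else ptau_obj,
                         params$ptau_thread_max_area_px,
                         params$ptau_tangle_max_area_px, cfg$pixel_size_um)
  summary_row <- aggregate_section(microglia, astro, ptcls, garea,
                                   donor_id = cfg$donor_id,
                                   n_tiles_accepted = length(accepted))
  utils::write.csv(summary_row, file.path(out_dir, "section_summary.csv"),
                   row.names = FALSE)
  manifest$stages$quantify <- list(gray_area_mm2 = garea,
                                   n_rows = nrow(summary_row))

  # -- associate (optional) ---------------------------------------------
  if (!is.null(cfg$traits) && file.exists(cfg$traits)) {
    traits <- utils::read.csv(cfg$traits, stringsAsFactors = FALSE)
    merged <- merge(summary_row, traits, by = "donor_id")
    manifest$stages$associate <- list(n_donors = nrow(merged))
    utils::write.csv(merged, file.path(out_dir, "associations_input.csv"),
                     row.names = FALSE)
  }

  manifest$elapsed_s <- as.numeric(Sys.time() - t_all, units = "secs")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
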