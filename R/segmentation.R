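# Per-tile object segmentation: nuclei, microglia (two-step), astrocytes,
# and phospho-tau deposits. The stages mirror the classic CellProfiler
# module sequence (IdentifyPrimaryObjects with shape or intensity
# declumping, tubeness enhancement, SplitOrMergeObjects, propagation-grown
# secondary objects, RelateObjects), reimplemented here.

#' Default segmentation parameters
#'
#' All printed pipeline constants in one place. Diameter ranges are in
#' pixels at the 20X scale (0.325 um/px): nuclei 18-80, microglia nuclei
#' < 40 (13.0 um), cytoplasm fragments 10-40 linked within 60 px (19.5 um),
#' astrocytes 10-300 with a 50-px line-structure feature size and tubeness
#' scale 2.0, phospho-tau 1-80 with a 20-SD robust background threshold and
#' the 900 / 10,000 px^2 thread/tangle area partition.
#'
#' @param ... Named overrides of any default.
#' @return List of class `seg_params`.
#' @export
seg_params <- function(...) {
  p <- list(
    nucleus_diam_px = c(18, 80),
    microglia_nucleus_max_equiv_diam_px = 40,
    iba1_sd_multiplier = 2,
    fragment_diam_px = c(10, 40),
    fragment_link_radius_px = 60,
    tubeness_scale_microglia = 4,
    astro_diam_px = c(10, 300),
    astro_feature_size_px = 50,
    astro_tubeness_scale = 2.0,
    ptau_diam_px = c(1, 80),
    ptau_sd_multiplier = 20,
    ptau_thread_max_area_px = 900,
    ptau_tangle_max_area_px = 10000,
    merge_radius_px = 10,
    propagate_lambda = 0.05,
    adaptive_block_px = 256,
    robust_trim = c(0.05, 0.05)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown))
    stop("unknown segmentation parameter(s): ",
         paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  for (nm in c("nucleus_diam_px", "fragment_diam_px", "astro_diam_px",
               "ptau_diam_px"))
    if (p[[nm]][1] >= p[[nm]][2]) stop(nm, ": range must have low < high")
  structure(p, class = "seg_params")
}

as_matrix <- function(x) matrix(as.numeric(x), nrow(x), ncol(x))

#' Identify primary objects by thresholding and declumping
#'
#' Thresholds the raster (Otsu or robust background; foreground strictly
#' above the threshold), splits clumped objects and filters by equivalent
#' diameter. Declumping methods:
#' \describe{
#'   \item{shape}{watershed on the Gaussian-smoothed distance transform
#'     (sigma = min diameter / 4), with watershed maxima suppressed within
#'     half the minimum diameter — splits touching round objects along the
#'     neck between their distance peaks.}
#'   \item{intensity}{the same watershed on the smoothed masked intensity —
#'     splits clumps at intensity saddles.}
#'   \item{none}{8-connected component labeling only.}
#' }
#'
#' @param img Numeric intensity matrix.
#' @param diam_range Equivalent-diameter range `c(low, high)` in px;
#'   objects outside it are discarded (inclusive bounds).
#' @param threshold_method `"otsu"` or `"robust_background"`.
#' @param declump_method `"shape"`, `"intensity"` or `"none"`.
#' @param threshold_args Extra arguments for the threshold function (e.g.
#'   `sd_multiplier`).
#' @param declump_tolerance Watershed merging tolerance; defaults to 1 px
#'   for shape declumping and, for intensity declumping, to 0.02 of the
#'   foreground intensity range (shallow saddles split, so clumped ridge
#'   networks separate into fragments).
#' @param object_class Class stamped on the output [label_map()].
#' @return A [label_map()]; an empty foreground yields 0 objects.
#' @export
identify_primary_objects <- function(img, diam_range,
                                     threshold_method = c("otsu", "robust_background"),
                                     declump_method = c("shape", "intensity", "none"),
                                     threshold_args = list(),
                                     declump_tolerance = NULL,
                                     object_class = "nucleus") {
  threshold_method <- match.arg(threshold_method)
  declump_method <- match.arg(declump_method)
  thr <- tryCatch(
    do.call(switch(threshold_method,
                   otsu = otsu_threshold,
                   robust_background = robust_background_threshold),
            c(list(img), threshold_args)),
    error = function(e) Inf)   # degenerate (constant) image -> no foreground
  bw <- img > thr
  if (!any(bw))
    return(label_map(matrix(0L, nrow(img), ncol(img)), object_class))
  min_d <- diam_range[1]
  sigma <- max(min_d / 4, 0.5)
  ext <- max(1L, as.integer(ceiling(min_d / 2)))
  # components below the minimum object area can never survive the size
  # filter; removing them up front keeps noise specks out of the
  # watershed's merge neighborhood
  min_area <- pi * (min_d / 2)^2
  comp <- label8(bw)
  small <- which(tabulate(comp[comp > 0L]) < min_area)
  if (length(small)) bw[comp %in% small] <- FALSE
  if (!any(bw))
    return(label_map(matrix(0L, nrow(img), ncol(img)), object_class))
  if (declump_method == "none") {
    lab <- label8(bw)
  } else if (declump_method == "shape") {
    d <- EBImage::distmap(bw * 1)
    ds <- EBImage::gblur(d, sigma = sigma)
    ds[!bw] <- 0
    tol <- if (is.null(declump_tolerance)) 1 else declump_tolerance
    lab <- EBImage::watershed(ds, tolerance = tol, ext = ext)
  } else {
    s <- EBImage::gblur(as_matrix(img), sigma = sigma)
    s[!bw] <- 0
    # tolerance is a fraction of the foreground intensity range, so the
    # declumping depth is invariant to intensity rescaling
    rel <- if (is.null(declump_tolerance)) 0.02 else declump_tolerance
    tol <- rel * max(diff(range(s[bw])), .Machine$double.eps)
    lab <- EBImage::watershed(s, tolerance = tol, ext = ext)
  }
  lab <- matrix(as.integer(lab), nrow(img), ncol(img))
  n <- max(lab)
  if (n > 0L) {
    areas <- tabulate(lab[lab > 0L], nbins = n)
    ed <- equivalent_diameter(areas)
    drop <- which(ed < diam_range[1] | ed > diam_range[2] | areas == 0)
    if (length(drop)) lab[lab %in% drop] <- 0L
  }
  label_map(lab, object_class)
}

#' Select microglia nuclei by size and IBA1 intensity
#'
#' Keeps nuclei with equivalent diameter strictly below
#' `max_equiv_diam_px` *and* mean IBA1 intensity strictly above the mean +
#' `sd_multiplier` SD of the IBA1 mean intensities over the reference
#' nucleus population. By default the population is the nuclei of the tile
#' itself; for a donor section, pass the pooled per-nucleus IBA1 means of
#' all accepted tiles as `population_iba1` (per-tile statistics are
#' unstable at ~50 nuclei per tile).
#'
#' @param nuclei [label_map()] of nuclei from [identify_primary_objects()].
#' @param iba1 IBA1 intensity raster.
#' @param max_equiv_diam_px Strict upper bound on equivalent diameter
#'   (default 40 px = 13.0 um).
#' @param sd_multiplier SD multiplier of the intensity gate (default 2).
#' @param population_iba1 Optional numeric vector of per-nucleus IBA1 mean
#'   intensities defining the gate population.
#' @return List: `labels` (microglia-nucleus [label_map()]), `table`
#'   (per-selected-nucleus features incl. `mean_IBA1`), `threshold`,
#'   `keep` (logical per input nucleus).
#' @export
select_microglia_nuclei <- function(nuclei, iba1, max_equiv_diam_px = 40,
                                    sd_multiplier = 2,
                                    population_iba1 = NULL) {
  stopifnot(inherits(nuclei, "LabelMap"))
  stk <- channel_stack(list(IBA1 = as_matrix(iba1)), tile_id = "gate")
  tab <- measure_objects(nuclei, stk)
  pop <- if (is.null(population_iba1)) tab$mean_IBA1 else population_iba1
  if (length(pop) < 3L)
    stop("insufficient population: need at least 3 nuclei for the IBA1 gate")
  threshold <- mean(pop) + sd_multiplier * stats::sd(pop)
  keep <- tab$equiv_diam_px < max_equiv_diam_px & tab$mean_IBA1 > threshold
  lab <- nuclei$labels
  lab[!(lab %in% tab$label[keep])] <- 0L
  out <- label_map(lab, "microglia_nucleus")
  sel <- tab[keep, , drop = FALSE]
  if (nrow(sel)) {
    sel$label <- seq_len(nrow(sel))   # relabeled contiguously
    sel$class <- "microglia_nucleus"
  }
  list(labels = out, table = sel, threshold = threshold, keep = keep)
}

#' Hessian ridge ("tubeness") enhancement of curvilinear structures
#'
#' Gaussian-smooths the raster at `sigma = scale`, computes the per-pixel
#' Hessian eigenvalues and returns `max(0, -lambda_low)` where
#' `lambda_low` is the more negative eigenvalue: bright ridges (glial
#' processes, tau threads) respond strongly, flat regions and the
#' interiors of large blobs respond weakly.
#'
#' @param img Numeric intensity matrix.
#' @param scale Smoothing scale sigma in pixels (> 0).
#' @return Non-negative matrix, same dimensions as `img`.
#' @export
enhance_tubeness <- function(img, scale) {
  stopifnot(scale > 0)
  g <- EBImage::gblur(as_matrix(img), sigma = scale)
  g <- matrix(as.numeric(g), nrow(img), ncol(img))
  nr <- nrow(g); nc <- ncol(g)
  up <- g[c(1L, 1:(nr - 1L)), ]; dn <- g[c(2:nr, nr), ]       # replicate pad
  lf <- g[, c(1L, 1:(nc - 1L))]; rt <- g[, c(2:nc, nc)]
  gyy <- up + dn - 2 * g
  gxx <- lf + rt - 2 * g
  ul <- g[c(1L, 1:(nr - 1L)), c(1L, 1:(nc - 1L))]
  ur <- g[c(1L, 1:(nr - 1L)), c(2:nc, nc)]
  dl <- g[c(2:nr, nr), c(1L, 1:(nc - 1L))]
  dr <- g[c(2:nr, nr), c(2:nc, nc)]
  gxy <- (dr + ul - ur - dl) / 4
  disc <- sqrt(((gxx - gyy) / 2)^2 + gxy^2)
  lambda_low <- (gxx + gyy) / 2 - disc
  # gamma-normalized (sigma^2) so responses are comparable across scales
  # and stay on an intensity-like scale
  matrix(scale^2 * pmax(0, -lambda_low), nr, nc)
}

#' Assemble microglia from nuclei and cytoplasm fragments
#'
#' Each IBA1 cytoplasm fragment is assigned to the microglia nucleus with
#' the smallest centroid-to-centroid distance, provided that distance is
#' within `link_radius_px` (default 60 px = 19.5 um); more distant
#' fragments are dropped. A fragment equidistant (within 1e-6 px) from two
#' nuclei goes to the lower nucleus label. Each microglia object is the
#' union of its nucleus and assigned fragments, labeled by nucleus, so the
#' microglia count equals the selected-nucleus count.
#'
#' @param fragments [label_map()] of cytoplasm fragments (from
#'   [identify_primary_objects()] on the tubeness-enhanced IBA1 channel,
#'   diameters 10-40, robust background, intensity declumping).
#' @param microglia_nuclei [label_map()] of selected microglia nuclei.
#' @param link_radius_px Maximum linking distance in pixels.
#' @param stack Optional [channel_stack()] for intensity features.
#' @param tile_id Tile identifier for the feature table.
#' @return List: `labels` (microglia [label_map()]), `objects` (feature
#'   table), `assignment` (per-fragment nucleus label or NA).
#' @export
assemble_microglia <- function(fragments, microglia_nuclei,
                               link_radius_px = 60, stack = NULL,
                               tile_id = NULL) {
  stopifnot(inherits(fragments, "LabelMap"),
            inherits(microglia_nuclei, "LabelMap"))
  nn <- microglia_nuclei$n_objects
  nf <- fragments$n_objects
  dims <- dim(microglia_nuclei$labels)
  if (nn == 0L) {
    lm <- label_map(matrix(0L, dims[1], dims[2]), "microglia")
    return(list(labels = lm,
                objects = measure_objects(lm, stack, tile_id),
                assignment = rep(NA_integer_, nf)))
  }
  ntab <- measure_objects(microglia_nuclei)
  assignment <- rep(NA_integer_, nf)
  if (nf > 0L) {
    ftab <- measure_objects(fragments)
    for (i in seq_len(nf)) {
      d <- sqrt((ftab$centroid_x[i] - ntab$centroid_x)^2 +
                  (ftab$centroid_y[i] - ntab$centroid_y)^2)
      j <- min(which(d <= min(d) + 1e-6))    # tie-break: lower label
      if (d[j] <= link_radius_px) assignment[i] <- ntab$label[j]
    }
  }
  out <- microglia_nuclei$labels
  if (nf > 0L && any(!is.na(assignment))) {
    fl <- fragments$labels
    map <- rep(0L, nf)
    map[which(!is.na(assignment))] <- assignment[!is.na(assignment)]
    add <- fl > 0L & out == 0L
    out[add] <- map[fl[add]]
  }
  lm <- label_map(out, "microglia", relabel = TRUE)
  list(labels = lm, objects = measure_objects(lm, stack, tile_id),
       assignment = assignment)
}

# Merge labeled objects whose boundary distance is <= radius; the merged
# group keeps the label of its largest member. Pure-spatial propagation
# grows every object by radius/2; grown objects that touch are unioned.
merge_nearby_objects <- function(labelmap, radius) {
  stopifnot(inherits(labelmap, "LabelMap"))
  lab <- labelmap$labels
  n <- labelmap$n_objects
  if (n < 2L) return(labelmap)
  bg_dist <- EBImage::distmap((lab == 0L) * 1)   # distance of bg px to objects
  mask <- lab > 0L | (matrix(as.numeric(bg_dist), nrow(lab), ncol(lab)) <= radius / 2)
  grown <- EBImage::propagate(matrix(0, nrow(lab), ncol(lab)),
                              seeds = lab, mask = mask, lambda = 1)
  grown <- matrix(as.integer(grown), nrow(lab), ncol(lab))
  pairs <- adjacent_label_pairs(grown, diagonal = TRUE)
  if (is.null(pairs) || nrow(pairs) == 0L) return(labelmap)
  comp <- uf_merge_pairs(n, pairs)
  areas <- tabulate(lab[lab > 0L], nbins = n)
  # representative of each component: its largest original object
  rep_of <- vapply(unique(comp), function(cmp) {
    members <- which(comp == cmp)
    members[which.max(areas[members])]
  }, integer(1))
  names(rep_of) <- unique(comp)
  map <- rep_of[as.character(comp)]
  label_map(apply_label_map(lab, map), labelmap$object_class)
}

# Robust-background threshold computed per block and bilinearly blended
# across the raster (adaptive threshold strategy).
adaptive_threshold <- function(img, block = 256L, lower_trim = 0.05,
                               upper_trim = 0.05, sd_multiplier = 2) {
  nr <- nrow(img); nc <- ncol(img)
  rb <- max(1L, ceiling(nr / block)); cb <- max(1L, ceiling(nc / block))
  if (rb == 1L && cb == 1L) {
    t0 <- robust_background_threshold(img, lower_trim, upper_trim,
                                      sd_multiplier)
    return(matrix(t0, nr, nc))
  }
  rcent <- (seq_len(rb) - 0.5) * nr / rb
  ccent <- (seq_len(cb) - 0.5) * nc / cb
  tgrid <- matrix(0, rb, cb)
  for (i in seq_len(rb)) for (j in seq_len(cb)) {
    rs <- max(1L, floor((i - 1) * nr / rb) + 1L):min(nr, ceiling(i * nr / rb))
    cs <- max(1L, floor((j - 1) * nc / cb) + 1L):min(nc, ceiling(j * nc / cb))
    tgrid[i, j] <- robust_background_threshold(img[rs, cs], lower_trim,
                                               upper_trim, sd_multiplier)
  }
  rq <- pmin(pmax(seq_len(nr), rcent[1]), rcent[rb])
  cq <- pmin(pmax(seq_len(nc), ccent[1]), ccent[cb])
  pracma::interp2(x = ccent, y = rcent, Z = tgrid,
                  xp = rep(cq, each = nr), yp = rep(rq, times = nc),
                  method = "linear") |>
    matrix(nrow = nr, ncol = nc)
}

#' Segment astrocytes from the GFAP channel
#'
#' Reproduces the multi-stage ramification-preserving workflow:
#' (1) line-structure enhancement of GFAP by white top-hat with a disc of
#' diameter `astro_feature_size_px`; (2) primary objects of equivalent
#' diameter 10-300 px (robust background threshold); (3) merge of objects
#' within `merge_radius_px` into their largest neighbor; (4) tubeness
#' enhancement at sigma = `astro_tubeness_scale`; (5) propagation-grown
#' secondary objects seeded by the merged primaries inside an adaptive
#' (per-block, bilinearly blended) robust-background mask of the tubeness
#' image; (6) a final ramification merge; (7) retention of only those
#' objects overlapping at least one nucleus.
#'
#' @param gfap GFAP intensity raster.
#' @param nuclei [label_map()] of nuclei (the DAPI gate).
#' @param params [seg_params()].
#' @param stack Optional [channel_stack()] for intensity features.
#' @param tile_id Tile identifier.
#' @return List: `labels` (astrocyte [label_map()]), `objects` (feature
#'   table including `mean_GFAP` when `stack` is given).
#' @export
segment_astrocytes <- function(gfap, nuclei, params = seg_params(),
                               stack = NULL, tile_id = NULL) {
  stopifnot(inherits(nuclei, "LabelMap"))
  fs <- 2L * floor(params$astro_feature_size_px / 2) + 1L
  enh <- EBImage::whiteTopHat(as_matrix(gfap),
                              EBImage::makeBrush(fs, "disc"))
  enh <- matrix(as.numeric(enh), nrow(gfap), ncol(gfap))
  prim <- identify_primary_objects(enh, params$astro_diam_px,
                                   "robust_background", "none",
                                   threshold_args = list(
                                     lower_trim = params$robust_trim[1],
                                     upper_trim = params$robust_trim[2]),
                                   object_class = "astrocyte")
  if (prim$n_objects == 0L)
    return(list(labels = prim, objects = measure_objects(prim, stack, tile_id)))
  merged <- merge_nearby_objects(prim, params$merge_radius_px)
  tub <- enhance_tubeness(gfap, params$astro_tubeness_scale)
  tmask <- tub > adaptive_threshold(tub, params$adaptive_block_px,
                                    params$robust_trim[1],
                                    params$robust_trim[2], 2)
  mask <- tmask | merged$labels > 0L
  sec <- EBImage::propagate(as_matrix(tub), seeds = merged$labels,
                            mask = mask, lambda = params$propagate_lambda)
  sec <- label_map(matrix(as.integer(sec), nrow(gfap), ncol(gfap)),
                   "astrocyte")
  final <- merge_nearby_objects(sec, params$merge_radius_px)
  # nucleus gate: keep objects overlapping >= 1 nucleus pixel
  over <- unique(final$labels[final$labels > 0L & nuclei$labels > 0L])
  lab <- final$labels
  lab[!(lab %in% over)] <- 0L
  out <- label_map(lab, "astrocyte")
  list(labels = out, objects = measure_objects(out, stack, tile_id))
}

#' Segment phospho-tau (AT8) deposits
#'
#' Robust-background threshold with a high SD multiplier (default 20) and
#' primary objects of equivalent diameter 1-80 px; no nucleus requirement.
#'
#' @param at8 pTau (AT8) intensity raster.
#' @param params [seg_params()].
#' @return A [label_map()] of class `ptau` (possibly empty).
#' @export
segment_ptau <- function(at8, params = seg_params()) {
  identify_primary_objects(
    at8, params$ptau_diam_px, "robust_background", "none",
    threshold_args = list(lower_trim = params$robust_trim[1],
                          upper_trim = params$robust_trim[2],
                          sd_multiplier = params$ptau_sd_multiplier),
    object_class = "ptau")
}

#' Classify phospho-tau objects into threads and tangles
#'
#' Area < 900 px^2: thread; 900 <= area < 10,000: tangle; area >= 10,000:
#' unclassified (excluded from the thread/tangle counts but retained in
#' the area-occupied readout). Boundary conventions: an area of exactly
#' 900 is a tangle, exactly 10,000 is unclassified. "Area occupied" is the
#' total segmented pTau area over all objects, in mm^2.
#'
#' @param objects Feature table with an `area_px` column (e.g. from
#'   [measure_objects()]).
#' @param thread_max_area_px,tangle_max_area_px Partition bounds.
#' @param pixel_size_um Pixel size for the area-occupied conversion.
#' @return List: `objects` (with a `ptau_class` column), `counts` (named:
#'   threads, tangles, unclassified), `area_occupied_mm2`.
#' @export
classify_ptau <- function(objects, thread_max_area_px = 900,
                          tangle_max_area_px = 10000,
                          pixel_size_um = GQ_PIXEL_SIZE_UM) {
  cls <- character(nrow(objects))
  if (nrow(objects)) {
    a <- objects$area_px
    cls <- ifelse(a < thread_max_area_px, "thread",
                  ifelse(a < tangle_max_area_px, "tangle", "unclassified"))
  }
  objects$ptau_class <- cls
  counts <- c(threads = sum(cls == "thread"),
              tangles = sum(cls == "tangle"),
              unclassified = sum(cls == "unclassified"))
  area_occ <- if (nrow(objects)) sum(objects$area_px) * pixel_size_um^2 / 1e6
              else 0
  list(objects = objects, counts = counts, area_occupied_mm2 = area_occ)
}

#' Segment one tile end to end
#'
#' Convenience wrapper running the full per-tile chain: nuclei from DAPI,
#' microglia-nucleus selection (optionally against a pooled section
#' population), tubeness enhancement and fragment identification on IBA1,
#' microglia assembly, optional astrocyte segmentation, and pTau
#' segmentation + classification.
#'
#' @param stack A [channel_stack()] with channels DAPI, IBA1, AT8 (pTau)
#'   and optionally GFAP, CD74.
#' @param params [seg_params()].
#' @param population_iba1 Optional pooled per-nucleus IBA1 means for the
#'   microglia-nucleus gate.
#' @param astrocytes Run the astrocyte stage (default TRUE when GFAP is
#'   present).
#' @return List with label maps and feature tables per object class.
#' @export
segment_tile <- function(stack, params = seg_params(),
                         population_iba1 = NULL,
                         astrocytes = "GFAP" %in% names(stack$channels)) {
  require_channels(stack, c("DAPI", "IBA1", "AT8"))
  dapi <- stack$channels$DAPI
  iba1 <- stack$channels$IBA1
  nuclei <- identify_primary_objects(
    dapi, params$nucleus_diam_px, "robust_background", "shape",
    threshold_args = list(lower_trim = params$robust_trim[1],
                          upper_trim = params$robust_trim[2]))
  nuc_tab <- measure_objects(nuclei, stack)
  mg <- NULL; mg_nuc <- NULL; frag <- NULL
  sel <- tryCatch(
    select_microglia_nuclei(nuclei, iba1,
                            params$microglia_nucleus_max_equiv_diam_px,
                            params$iba1_sd_multiplier, population_iba1),
    error = function(e) NULL)
  if (!is.null(sel)) {
    mg_nuc <- sel$labels
    tub <- enhance_tubeness(iba1, params$tubeness_scale_microglia)
    frag <- identify_primary_objects(
      tub, params$fragment_diam_px, "robust_background", "intensity",
      threshold_args = list(lower_trim = params$robust_trim[1],
                            upper_trim = params$robust_trim[2]),
      object_class = "microglia_fragment")
    mg <- assemble_microglia(frag, mg_nuc, params$fragment_link_radius_px,
                             stack, stack$tile_id)
  }
  astro <- NULL
  if (isTRUE(astrocytes)) {
    require_channels(stack, "GFAP")
    astro <- segment_astrocytes(stack$channels$GFAP, nuclei, params,
                                stack, stack$tile_id)
  }
  pt_lab <- segment_ptau(stack$channels$AT8, params)
  pt <- classify_ptau(measure_objects(pt_lab, stack, stack$tile_id),
                      params$ptau_thread_max_area_px,
                      params$ptau_tangle_max_area_px,
                      stack$pixel_size_um)
  list(nuclei = nuclei, nucleus_table = nuc_tab,
       microglia_nuclei = mg_nuc, fragments = frag, microglia = mg,
       astrocytes = astro, ptau = pt)
}
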