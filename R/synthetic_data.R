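# Seeded synthetic-data generator: five-channel 20X tiles, 4X whole-slide
# brightfield/DAPI pairs, and donor cohorts, each with ground-truth tables,
# so every pipeline stage is testable without microscope data.
#
# All shape and intensity distributions are invented stand-ins for real
# immunofluorescence; every parameter is surfaced in the params lists with
# documented defaults, and a single seed governs all randomness.

# ---- low-level raster painting ----------------------------------------

paint_disk <- function(img, cy, cx, r, value) {
  nr <- nrow(img); nc <- ncol(img)
  r_ <- ceiling(r)
  r1 <- max(1L, floor(cy - r_)); r2 <- min(nr, ceiling(cy + r_))
  c1 <- max(1L, floor(cx - r_)); c2 <- min(nc, ceiling(cx + r_))
  if (r1 > r2 || c1 > c2) return(img)
  rs <- r1:r2; cs <- c1:c2
  sub <- img[rs, cs, drop = FALSE]
  d2 <- outer((rs - cy)^2, (cs - cx)^2, "+")
  sel <- d2 <= r^2
  sub[sel] <- pmax(sub[sel], value)
  img[rs, cs] <- sub
  img
}

paint_ellipse <- function(img, cy, cx, ry, rx, theta, value) {
  nr <- nrow(img); nc <- ncol(img)
  rmax <- ceiling(max(rx, ry))
  r1 <- max(1L, floor(cy - rmax)); r2 <- min(nr, ceiling(cy + rmax))
  c1 <- max(1L, floor(cx - rmax)); c2 <- min(nc, ceiling(cx + rmax))
  if (r1 > r2 || c1 > c2) return(img)
  rs <- r1:r2; cs <- c1:c2
  yy <- matrix(rs - cy, length(rs), length(cs))
  xx <- matrix(cs - cx, length(rs), length(cs), byrow = TRUE)
  u <- cos(theta) * xx + sin(theta) * yy
  v <- -sin(theta) * xx + cos(theta) * yy
  sel <- (u / rx)^2 + (v / ry)^2 <= 1
  sub <- img[rs, cs, drop = FALSE]
  sub[sel] <- pmax(sub[sel], value)
  img[rs, cs] <- sub
  img
}

# random-walk curvilinear stroke of given length / width. Staining along
# glial processes is varicose (beads on a string), so the stroke intensity
# is modulated every few steps by `varicosity`.
paint_walk <- function(img, cy, cx, theta, length_px, width_px, value,
                       jitter_sd = 0.15, varicosity = 0) {
  pos <- c(cy, cx)
  w <- width_px / 2
  m <- 1
  for (s in seq_len(round(length_px))) {
    theta <- theta + stats::rnorm(1, 0, jitter_sd)
    pos <- pos + c(sin(theta), cos(theta))
    if (varicosity > 0 && s %% 5L == 1L)
      m <- stats::runif(1, 1 - varicosity, 1 + varicosity / 3)
    img <- paint_disk(img, pos[1], pos[2], max(w, 0.6), value * m)
  }
  img
}

smooth_background <- function(nr, nc, base, gradient_amp) {
  phi <- stats::runif(1, 0, 2 * pi)
  gx <- cos(phi); gy <- sin(phi)
  ramp <- outer(seq_len(nr) / nr, seq_len(nc) / nc,
                function(y, x) gy * y + gx * x)
  base + gradient_amp * (ramp - mean(ramp))
}

finish_channel <- function(img, blur_sigma, noise_sd) {
  if (blur_sigma > 0)
    img <- matrix(as.numeric(EBImage::gblur(img, sigma = blur_sigma)),
                  nrow(img), ncol(img))
  img <- img + matrix(stats::rnorm(length(img), 0, noise_sd),
                      nrow(img), ncol(img))
  pmin(pmax(img, 0), 1)
}

# place n points uniformly; pairwise separation respects per-point radii
# (plus a clearance gap) and a global floor, so rendered nuclei never
# interpenetrate
place_points <- function(n, nr, nc, min_sep, margin, radius = NULL,
                         gap = 6, max_tries = 1000L) {
  if (n == 0L) return(cbind(y = numeric(0), x = numeric(0)))
  if (is.null(radius)) radius <- rep(0, n)
  ys <- numeric(0); xs <- numeric(0); rs <- numeric(0)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      y <- stats::runif(1, margin, nr - margin)
      x <- stats::runif(1, margin, nc - margin)
      sep <- pmax(min_sep, rs + radius[i] + gap)
      if (!length(ys) || all((ys - y)^2 + (xs - x)^2 >= sep^2)) {
        ys <- c(ys, y); xs <- c(xs, x); rs <- c(rs, radius[i])
        placed <- TRUE; break
      }
    }
    if (!placed)
      stop("placement error: object density too high for the tile size")
  }
  cbind(y = ys, x = xs)
}

# ---- tile generator ----------------------------------------------------

#' Default parameters of the synthetic tile generator
#'
#' Densities emulate human dorsolateral prefrontal cortex gray matter at
#' a typical microglial density of 48 cells per mm^2 of a 6 um section;
#' other nuclei (neurons, other glia) and astrocytes are set to realistic
#' desk-scale proportions so that microglia are a ~10% minority of nuclei.
#' The CD74-high subpopulation is planted at fraction `f_cd74_high` with
#' its mean shifted far above the CD74-low mean (well beyond +3 SD of the
#' low component).
#'
#' @param ... Named overrides.
#' @return List of class `sim_tile_params`.
#' @export
sim_tile_params <- function(...) {
  p <- list(
    size_px = 510L,
    pixel_size_um = GQ_PIXEL_SIZE_UM,
    microglia_per_mm2 = 48,
    other_nuclei_per_mm2 = 500,
    astrocytes_per_mm2 = 60,
    ptau_threads_per_mm2 = 10,
    ptau_tangles_per_mm2 = 3,
    f_cd74_high = 0.05,
    f_ameboid = 0.05,
    cd74_low_mean = 0.10, cd74_low_sd = 0.015,
    cd74_high_mean = 0.80, cd74_high_sd = 0.05,
    dapi_intensity = c(0.45, 0.70),
    iba1_intensity = c(0.55, 0.70),
    gfap_intensity = c(0.40, 0.55),
    at8_intensity = c(0.45, 0.70),
    nucleus_diam_px = c(24, 38),
    microglia_nucleus_diam_px = c(18, 26),
    soma_radius_px = c(8, 14),
    n_processes = c(2L, 6L),
    process_length_px = c(20, 60),
    process_width_px = c(1, 2),
    astro_arms = c(6L, 9L),
    astro_arm_length_px = c(25, 60),
    min_sep_px = 20,
    margin_px = 30,
    base_background = 0.02,
    bg_gradient_amp = 0.012,
    noise_sd = 0.008,
    blur_sigma = 0.7,
    cd74_blur_sigma = 2,     # diffuse cytoplasmic stain, far-red PSF
    defect = "none"          # none | empty | blur | debris
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown))
    stop("unknown tile parameter(s): ", paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  structure(p, class = "sim_tile_params")
}

runif2 <- function(n, range) stats::runif(n, range[1], range[2])

# per-cell CD74 staining levels with a planted high component
draw_cd74_levels <- function(n, f_high, p = sim_tile_params()) {
  high <- stats::runif(n) < f_high
  lvl <- ifelse(high,
                stats::rnorm(n, p$cd74_high_mean, p$cd74_high_sd),
                stats::rnorm(n, p$cd74_low_mean, p$cd74_low_sd))
  list(level = pmax(lvl, 0.01), high = high)
}

#' Generate one synthetic five-channel tile with ground truth
#'
#' Renders DAPI ellipsoidal nuclei, microglia (IBA1 soma disk + 1-2 px
#' random-walk processes over a co-located nucleus), star-shaped GFAP
#' astrocytes over nuclei, curvilinear pTau threads and blob tangles in
#' AT8, and a CD74 channel whose per-cell staining carries a planted
#' high-expressing subpopulation. Object counts are Poisson draws at the
#' configured densities; realized counts are recorded in the ground-truth
#' table (so densities are always consistent with rendered objects). Each
#' channel receives a smooth background gradient, optical blur and
#' additive Gaussian noise. Fully reproducible from `seed`.
#'
#' @param params [sim_tile_params()].
#' @param seed Integer seed.
#' @param tile_id Tile identifier.
#' @return List: `stack` (a [channel_stack()] with channels DAPI, AT8,
#'   GFAP, IBA1, CD74), `truth` (list with `cells` data frame and
#'   `defect`).
#' @export
generate_tile <- function(params = sim_tile_params(), seed = 1L,
                          tile_id = "tile") {
  stopifnot(inherits(params, "sim_tile_params"))
  set.seed(seed)
  p <- params
  n <- p$size_px
  area_mm2 <- (n * p$pixel_size_um)^2 / 1e6
  ch <- lapply(1:5, function(i)
    smooth_background(n, n, p$base_background, p$bg_gradient_amp))
  names(ch) <- c("DAPI", "AT8", "GFAP", "IBA1", "CD74")

  cells <- data.frame(cell_id = integer(0), class = character(0),
                      x = numeric(0), y = numeric(0),
                      nucleus_diam_px = numeric(0), soma_r_px = numeric(0),
                      n_processes = integer(0), cd74_level = numeric(0),
                      cd74_high = logical(0), stringsAsFactors = FALSE)
  defect <- match.arg(p$defect, c("none", "empty", "blur", "debris"))

  if (defect != "empty") {
    n_mg <- stats::rpois(1, p$microglia_per_mm2 * area_mm2)
    n_other <- stats::rpois(1, p$other_nuclei_per_mm2 * area_mm2)
    n_ast <- stats::rpois(1, p$astrocytes_per_mm2 * area_mm2)
    n_thr <- stats::rpois(1, p$ptau_threads_per_mm2 * area_mm2)
    n_tgl <- stats::rpois(1, p$ptau_tangles_per_mm2 * area_mm2)
    kind <- rep(c("microglia", "other_nucleus", "astrocyte"),
                c(n_mg, n_other, n_ast))
    nds <- ifelse(kind == "microglia",
                  runif2(length(kind), p$microglia_nucleus_diam_px),
                  runif2(length(kind), p$nucleus_diam_px))
    # worst-case semi-axis of the nucleus ellipse is nd/2 / 0.8
    pts <- place_points(length(kind), n, n, p$min_sep_px, p$margin_px,
                        radius = nds * 0.63)
    cd74 <- draw_cd74_levels(length(kind), p$f_cd74_high, p)

    rec <- vector("list", nrow(pts))
    for (i in seq_len(nrow(pts))) {
      cy <- pts[i, 1]; cx <- pts[i, 2]
      cls <- kind[i]
      nd <- nds[i]
      ratio <- stats::runif(1, 0.8, 1)
      ry <- nd / 2 * ratio; rx <- nd / 2 / ratio
      ch$DAPI <- paint_ellipse(ch$DAPI, cy, cx, ry, rx,
                               stats::runif(1, 0, pi),
                               runif2(1, p$dapi_intensity))
      soma_r <- NA_real_; npr <- NA_integer_
      if (cls == "microglia") {
        # perinuclear cytoplasm: the IBA1 soma always wraps the nucleus
        soma_r <- max(runif2(1, p$soma_radius_px), nd / 2 + 2)
        v_iba <- runif2(1, p$iba1_intensity)
        mask_before <- ch$IBA1
        ch$IBA1 <- paint_disk(ch$IBA1, cy, cx, soma_r, v_iba)
        # CD74-high microglia take the rounded, process-retracted
        # (ameboid) morphology characteristic of activated cells
        ameboid <- cd74$high[i] || stats::runif(1) < p$f_ameboid
        npr <- if (ameboid) 0L
               else sample(p$n_processes[1]:p$n_processes[2], 1)
        th0 <- stats::runif(1, 0, 2 * pi)
        for (k in seq_len(npr)) {
          th <- th0 + 2 * pi * k / npr + stats::rnorm(1, 0, 0.3)
          ch$IBA1 <- paint_walk(ch$IBA1,
                                cy + soma_r * 0.8 * sin(th),
                                cx + soma_r * 0.8 * cos(th), th,
                                runif2(1, p$process_length_px),
                                runif2(1, p$process_width_px),
                                v_iba * 0.9, varicosity = 0.4)
        }
        # CD74 staining over the whole cell footprint (IBA1-positive px)
        cellpx <- which(ch$IBA1 > mask_before + 1e-9)
        cur <- ch$CD74[cellpx]
        ch$CD74[cellpx] <- pmax(cur, cd74$level[i])
      } else if (cls == "astrocyte") {
        soma_r <- stats::runif(1, 5, 8)
        v_gfap <- runif2(1, p$gfap_intensity)
        ch$GFAP <- paint_disk(ch$GFAP, cy, cx, soma_r, v_gfap)
        narm <- sample(p$astro_arms[1]:p$astro_arms[2], 1)
        th0 <- stats::runif(1, 0, 2 * pi)
        for (k in seq_len(narm)) {
          th <- th0 + 2 * pi * k / narm + stats::rnorm(1, 0, 0.2)
          ch$GFAP <- paint_walk(ch$GFAP,
                                cy + soma_r * 0.8 * sin(th),
                                cx + soma_r * 0.8 * cos(th), th,
                                runif2(1, p$astro_arm_length_px), 2,
                                v_gfap * 0.9, jitter_sd = 0.08)
        }
      }
      rec[[i]] <- data.frame(
        cell_id = i, class = cls, x = cx, y = cy, nucleus_diam_px = nd,
        soma_r_px = soma_r, n_processes = npr,
        morph_class = if (cls != "microglia") NA_character_
                      else if (npr == 0L) "ameboid" else "ramified",
        cd74_level = if (cls == "microglia") cd74$level[i] else NA_real_,
        cd74_high = if (cls == "microglia") cd74$high[i] else NA,
        stringsAsFactors = FALSE)
    }
    # pTau deposits: threads (thin curvilinear) and tangles (lumpy blobs)
    idx0 <- nrow(pts)
    ptau_rec <- list()
    if (n_thr + n_tgl > 0L) {
      ppts <- matrix(c(stats::runif(n_thr + n_tgl, p$margin_px, n - p$margin_px),
                       stats::runif(n_thr + n_tgl, p$margin_px, n - p$margin_px)),
                     ncol = 2)
      for (i in seq_len(n_thr + n_tgl)) {
        cy <- ppts[i, 1]; cx <- ppts[i, 2]
        v <- runif2(1, p$at8_intensity)
        if (i <= n_thr) {
          ch$AT8 <- paint_walk(ch$AT8, cy, cx, stats::runif(1, 0, 2 * pi),
                               stats::runif(1, 60, 180),
                               stats::runif(1, 1, 2), v, jitter_sd = 0.1)
          cls <- "ptau_thread"
        } else {
          r0 <- stats::runif(1, 16, 24)
          ch$AT8 <- paint_disk(ch$AT8, cy, cx, r0, v)
          for (k in 1:4)
            ch$AT8 <- paint_disk(ch$AT8,
                                 cy + stats::rnorm(1, 0, r0 / 2),
                                 cx + stats::rnorm(1, 0, r0 / 2),
                                 r0 * stats::runif(1, 0.4, 0.7), v)
          cls <- "ptau_tangle"
        }
        ptau_rec[[i]] <- data.frame(
          cell_id = idx0 + i, class = cls, x = cx, y = cy,
          nucleus_diam_px = NA_real_, soma_r_px = NA_real_,
          n_processes = NA_integer_, morph_class = NA_character_,
          cd74_level = NA_real_, cd74_high = NA, stringsAsFactors = FALSE)
      }
    }
    cells <- do.call(rbind, c(rec, ptau_rec))
    if (is.null(cells)) cells <- data.frame()
  }

  if (defect == "debris") {
    cy <- stats::runif(1, n * 0.3, n * 0.7)
    cx <- stats::runif(1, n * 0.3, n * 0.7)
    for (nm in names(ch)) {
      ch[[nm]] <- paint_disk(ch[[nm]], cy, cx, n * 0.18, 0.95)
      for (k in 1:3)
        ch[[nm]] <- paint_disk(ch[[nm]], cy + stats::rnorm(1, 0, n * 0.06),
                               cx + stats::rnorm(1, 0, n * 0.06),
                               n * stats::runif(1, 0.05, 0.12), 0.9)
    }
  }
  for (nm in names(ch)) {
    blur <- if (defect == "blur") 4
            else if (nm == "CD74") p$cd74_blur_sigma
            else p$blur_sigma
    ch[[nm]] <- finish_channel(ch[[nm]], blur, p$noise_sd)
  }

  list(stack = channel_stack(ch, pixel_size_um = p$pixel_size_um,
                             tile_id = tile_id),
       truth = list(cells = cells, defect = defect))
}

# ---- section generator -------------------------------------------------

#' Default parameters of the synthetic section generator
#'
#' A section is a 4X brightfield/DAPI pair containing one tissue blob with
#' a gray-matter region and a white-matter band, plus a grid of 20X tiles:
#' the upper rows sit wholly in gray matter, the bottom row straddles the
#' gray/white boundary (so it fails the 95% gray gate).
#'
#' @param ... Named overrides; `tile` may carry [sim_tile_params()]
#'   overrides as a list.
#' @return List of class `sim_section_params`.
#' @export
sim_section_params <- function(...) {
  p <- list(
    grid = c(2L, 3L),        # tiles (columns, rows)
    tile_px = 510L,
    scale_to_tile = 5,
    margin_4x = 60L,
    wm_band = TRUE,          # white-matter band through the bottom tile row
    brightfield_bg = 0.92,
    brightfield_gray = 0.35,
    brightfield_white = 0.60,
    dapi4x_bg = 0.01,
    dapi4x_gray = 0.35,
    dapi4x_white = 0.22,
    noise_sd = 0.01,
    tile = list()            # overrides for sim_tile_params()
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown))
    stop("unknown section parameter(s): ", paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  structure(p, class = "sim_section_params")
}

#' Generate a synthetic section: 4X pair, 20X tiles and ground truth
#'
#' @param params [sim_section_params()].
#' @param seed Integer seed; tile seeds are derived from it.
#' @param defects Optional character vector (length = number of tiles)
#'   of planted per-tile defects (`"none"`, `"empty"`, `"blur"`,
#'   `"debris"`).
#' @return List: `brightfield_4x`, `dapi_4x`, `tiles` (list of
#'   [channel_stack()] with `origin_xy` set), `truth` (tissue label
#'   raster, per-tile origins/gray fractions/defects, pooled cell table,
#'   gray area of the fully gray tiles, realized densities).
#' @export
generate_section <- function(params = sim_section_params(), seed = 1L,
                             defects = NULL) {
  stopifnot(inherits(params, "sim_section_params"))
  p <- params
  if (p$grid[1] < 1L || p$grid[2] < 1L) stop("empty section: grid must be >= 1x1")
  set.seed(seed)
  s <- p$scale_to_tile
  tp4 <- p$tile_px / s                      # tile size in 4X px
  if (tp4 != round(tp4)) stop("tile_px must be a multiple of scale_to_tile")
  nr4 <- as.integer(p$grid[2] * tp4 + 2 * p$margin_4x)
  nc4 <- as.integer(p$grid[1] * tp4 + 2 * p$margin_4x)

  # tissue blob: ellipse comfortably covering the tile grid
  yy <- matrix(seq_len(nr4), nr4, nc4)
  xx <- matrix(seq_len(nc4), nr4, nc4, byrow = TRUE)
  cy <- (nr4 + 1) / 2; cx <- (nc4 + 1) / 2
  tissue <- ((yy - cy) / (nr4 / 2 - 4))^2 + ((xx - cx) / (nc4 / 2 - 4))^2 <= 1
  labels <- matrix(0L, nr4, nc4)
  labels[tissue] <- 2L
  if (p$wm_band) {
    # boundary through the vertical middle of the bottom tile row
    y_wm <- p$margin_4x + (p$grid[2] - 0.5) * tp4
    labels[tissue & yy > y_wm] <- 1L
  }

  bf <- matrix(p$brightfield_bg, nr4, nc4)
  bf[labels == 2L] <- p$brightfield_gray
  bf[labels == 1L] <- p$brightfield_white
  d4 <- matrix(p$dapi4x_bg, nr4, nc4)
  d4[labels == 2L] <- p$dapi4x_gray
  d4[labels == 1L] <- p$dapi4x_white
  bf <- finish_channel(bf, 1, p$noise_sd)
  d4 <- finish_channel(d4, 1, p$noise_sd)

  n_tiles <- p$grid[1] * p$grid[2]
  if (is.null(defects)) defects <- rep("none", n_tiles)
  stopifnot(length(defects) == n_tiles)
  origins <- matrix(0, n_tiles, 2)
  gray_frac <- numeric(n_tiles)
  tiles <- vector("list", n_tiles)
  cell_tabs <- list()
  tile_seeds <- sample.int(.Machine$integer.max - 1L, n_tiles)
  k <- 0L
  for (ri in seq_len(p$grid[2])) for (ci in seq_len(p$grid[1])) {
    k <- k + 1L
    x0 <- (p$margin_4x + (ci - 1L) * tp4) * s    # 0-based 20X offsets
    y0 <- (p$margin_4x + (ri - 1L) * tp4) * s
    origins[k, ] <- c(x0, y0)
    rows4 <- (y0 / s + 1):(y0 / s + tp4)
    cols4 <- (x0 / s + 1):(x0 / s + tp4)
    gray_frac[k] <- mean(labels[rows4, cols4] == 2L)
    tl <- generate_tile(do.call(sim_tile_params,
                                c(p$tile, list(size_px = p$tile_px,
                                               defect = defects[k]))),
                        seed = tile_seeds[k],
                        tile_id = sprintf("tile_%02d", k))
    tl$stack$origin_xy <- c(x0, y0)
    tiles[[k]] <- tl$stack
    tc <- tl$truth$cells
    if (!is.null(tc) && nrow(tc)) {
      tc$tile_id <- sprintf("tile_%02d", k)
      tc$tile_index <- k
      cell_tabs[[k]] <- tc
    }
  }
  cells <- if (length(cell_tabs)) do.call(rbind, cell_tabs) else data.frame()

  px_um <- GQ_PIXEL_SIZE_UM
  tile_area_mm2 <- (p$tile_px * px_um)^2 / 1e6
  fully_gray <- which(gray_frac > 0.95 & defects == "none")
  n_mg_gray <- if (nrow(cells))
    sum(cells$class == "microglia" & cells$tile_index %in% fully_gray) else 0L
  truth <- list(
    tissue_labels = labels,
    pixel_size_4x_um = px_um * s,
    tile_origins = origins, tile_px = p$tile_px,
    tile_gray_frac = gray_frac, defects = defects,
    cells = cells,
    tissue_area_mm2 = sum(labels > 0L) * (px_um * s)^2 / 1e6,
    gray_area_mm2 = sum(labels == 2L) * (px_um * s)^2 / 1e6,
    accepted_tiles = fully_gray,
    accepted_gray_area_mm2 = length(fully_gray) * tile_area_mm2,
    n_microglia_accepted = n_mg_gray,
    microglia_density_per_mm2 = if (length(fully_gray))
      n_mg_gray / (length(fully_gray) * tile_area_mm2) else NA_real_)
  list(brightfield_4x = bf, dapi_4x = d4, tiles = tiles, truth = truth)
}

# ---- cohort generator --------------------------------------------------

#' Generate a synthetic donor cohort with longitudinal cognition
#'
#' Plants a linear effect of the CD74-high percentage on the annual rate
#' of cognitive decline and a CD74-high difference between donors dying
#' in terminal decline vs. earlier, then simulates annual cognitive
#' scores per donor from subject-level intercepts and slopes.
#'
#' @param n_donors Number of donors (>= 2).
#' @param effect List: `beta_cd74` (slope change per CD74-high
#'   percentage point, default -0.01), `terminal_pct_diff` (CD74-high
#'   percentage-point difference of the terminal-decline group, default
#'   2), `base_slope`, `resid_sd`, `visit_noise_sd`, `n_visits`.
#' @param seed Integer seed.
#' @return List: `donors` (one row per donor: phenotypes, covariates,
#'   traits, true `cognitive_slope`), `scores` (long table subject /
#'   time / score / group).
#' @export
generate_cohort <- function(n_donors = 60L, effect = list(), seed = 1L) {
  if (n_donors < 2L) stop("need at least 2 donors")
  ef <- utils::modifyList(
    list(beta_cd74 = -0.01, terminal_pct_diff = 2, base_slope = -0.05,
         resid_sd = 0.03, visit_noise_sd = 0.1, n_visits = 8L), effect)
  set.seed(seed)
  terminal <- stats::rbinom(n_donors, 1, 0.5)
  pct_cd74 <- pmax(0.5, 5 + 1.5 * stats::rnorm(n_donors) +
                     ef$terminal_pct_diff * terminal)
  age <- round(stats::rnorm(n_donors, 85, 6), 1)
  sex <- stats::rbinom(n_donors, 1, 0.6)
  pmi <- round(pmax(2, stats::rnorm(n_donors, 8, 3)), 1)
  background_level <- stats::rbinom(n_donors, 1, 0.5)
  slope <- ef$base_slope + ef$beta_cd74 * (pct_cd74 - mean(pct_cd74)) -
    0.001 * (age - 85) + stats::rnorm(n_donors, 0, ef$resid_sd)
  donors <- data.frame(
    donor_id = sprintf("D%03d", seq_len(n_donors)),
    pct_cd74_high = pct_cd74,
    microglia_density_per_mm2 = stats::rnorm(n_donors, 48, 6),
    pct_rounded = pmax(0.2, stats::rnorm(n_donors, 5, 2)),
    ptau_area_occupied_mm2 = stats::rlnorm(n_donors, -3, 1),
    age = age, sex = sex, post_mortem_interval = pmi,
    background_level = background_level,
    pathologic_AD = stats::rbinom(n_donors, 1, 0.5),
    Braak = sample(0:6, n_donors, replace = TRUE),
    terminal_decline = terminal,
    cognitive_slope = slope,
    stringsAsFactors = FALSE)
  sc <- do.call(rbind, lapply(seq_len(n_donors), function(i) {
    t <- 0:(ef$n_visits - 1L)
    data.frame(subject = donors$donor_id[i], time = t,
               score = stats::rnorm(1, 0, 0.3) + slope[i] * t +
                 stats::rnorm(length(t), 0, ef$visit_noise_sd),
               group = ifelse(terminal[i] == 1, "terminal", "earlier"),
               stringsAsFactors = FALSE)
  }))
  list(donors = donors, scores = sc)
}
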