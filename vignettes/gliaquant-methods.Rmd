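---
title: "Quantifying microglia, astrocytes and phospho-tau in whole-slide immunofluorescence: methods and design"
author: "gliaquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gliaquant methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliaquant)
```

## The problem

Morphologically "activated" (stage III) microglia and microglia with high
CD74 (MHC class II invariant chain) expression are both of interest in
aging and Alzheimer's disease, but manual counting on tissue sections is
slow and rater-dependent. `gliaquant` implements an automated pipeline for
whole-slide, five-channel immunofluorescence scans of human cortex (DAPI,
pTau/AT8, GFAP, IBA1, CD74 at 20X, 0.325 µm/px, plus a 4X
brightfield/DAPI overview): it delineates gray matter, quality-controls
image tiles, segments nuclei, microglia, astrocytes and phospho-tau
deposits, measures per-object morphometry and marker intensities,
classifies CD74-high and morphologically rounded cells, and fits the
donor-level association statistics.

## Tissue identification and the gray-matter gate

Tissue absorbs light in brightfield and carries DAPI signal, so the
tissue mask is the pixel-wise intersection of the Otsu-binarized 4X
brightfield (below-threshold class; polarity is configurable) and DAPI
(above-threshold class). The mask is hole-filled and connected components
below 0.1 mm² are removed as dust; both cleanup steps are explicit,
configurable choices of this package. A second Otsu cut on the brightfield
intensities *within* tissue separates the darker, cell-dense gray matter
(label 2) from the brighter white matter (label 1).

A 20X tile enters analysis only if *strictly more than* 95% of its
footprint (mapped to the 4X grid by nearest neighbor; label rasters are
never interpolated) is gray matter. A fraction of exactly 0.95 is
rejected. The 4X→20X scale factor defaults to 5, the nominal
magnification ratio.

## Thresholding primitives

Two scalar thresholds are used throughout; pixels are foreground only if
strictly greater than the threshold, and "standard deviation" always
means the sample SD (n−1):

* **Otsu**: intensities are rescaled to [0, 1] and binned into 256
  histogram bins regardless of acquisition bit depth (for
  reproducibility across scanners); the returned threshold is the bin
  edge maximizing the between-class variance (lowest edge on ties).
* **Robust background**: sort, trim the lowest and highest 5% of pixels,
  return trimmed mean + k·SD. k = 2 for nuclei, microglia fragments and
  astrocytes; k = 20 for phospho-tau, whose sparse, very bright deposits
  sit far above the trimmed background. The 20-SD multiplier applies to
  the SD of the trimmed background, not of the full image — that is what
  the trimmed estimator means.

## Tile quality control

Three per-tile metrics: the IBA1 mean absolute deviation (near zero on
empty tiles), the power log-log slope of IBA1/GFAP/DAPI (OLS slope of
log radial-average power on log frequency over 5–45% of Nyquist in 32
log-spaced bins; defocus steepens the spectrum, so blur makes the slope
more negative), and the per-channel Otsu threshold (dragged upward by
bright debris).

Outlier tiles are traditionally excluded by visual inspection of these
metric distributions; automation needs an explicit rule. A tile is flagged only if its metric
is beyond the batch percentile cutoff (2nd / 98th by default) *and*
beyond a scale-free guard against the batch median (MAD below 0.35× the
median; slope more than 1.5 units below the median; Otsu threshold above
1.25× the median *and* above an absolute floor of 0.35 on the [0, 1]
scale — on sparse channels such as pTau the median threshold is nearly
zero, and without the floor genuine content would register as debris).
The guard exists because a pure percentile rule must
flag a fixed share of every batch, including defect-free ones; the
combined rule accepts homogeneous batches (almost surely) while gross
outliers — which planted defects are — satisfy both conditions. Flag
sets remain monotone in the percentile cutoffs. Batches under 20 tiles
fall back to absolute thresholds (stated for [0, 1]-normalized
intensities) with a warning.

## Segmentation

**Primary objects.** Threshold → despeckle → declump → size-filter.
Components smaller than the minimum object area are removed before
declumping: they could never pass the size filter, and leaving them in
lets the watershed's merge neighborhood chain noise specks into spurious
scattered objects. "Shape" declumping is a watershed on the
Gaussian-smoothed distance transform (σ = min diameter / 4) with maxima
suppression within half the minimum diameter; "Intensity" declumping is
the same watershed on the smoothed masked intensity with a merging
tolerance of 0.02 of the foreground intensity range — relative, so the
declumping depth is invariant to intensity rescaling. Objects are
8-connected; background is 4-connected. Surviving objects are filtered
to an equivalent-diameter range (inclusive bounds) and relabeled 1..n.
Segmentation is fully deterministic.

**Nuclei** are primary objects of the DAPI channel, diameters 18–80 px,
robust background threshold, shape declumping.

**Microglia** are built in two steps. (1) Nuclei with equivalent
diameter strictly below 40 px (13.0 µm) and mean IBA1 intensity strictly
above the mean + 2 SD of the per-nucleus IBA1 means are selected as
microglia nuclei. The reference population defaults to the donor
section's pooled accepted-tile nuclei, not the single tile: at ~50
nuclei per tile the mean+2SD estimate is unstable, and the section is
the natural unit for "all nuclei" (configurable). The mean is taken
within the nucleus mask; an expanded perinuclear ring would be a
defensible variant, but the mask is the parsimonious choice.
(2) The IBA1 channel is tubeness-enhanced (below), cytoplasm fragments
are identified on it (diameters 10–40 px, robust background, intensity
declumping), and each fragment is attached to the nearest microglia
nucleus by centroid-to-centroid distance if within 60 px (19.5 µm); ties
within 10⁻⁶ px go to the lower label, and farther fragments are
dropped. Centroid distance is the cheapest order-independent metric
compatible with "within 60 pixels". Every microglia object is the union
of one nucleus and its fragments — microglia count equals selected
nucleus count, and an assembled object may be spatially disconnected.

**Tubeness** is a single-scale Hessian ridge measure: Gaussian smoothing
at σ = scale, then max(0, −λ_low) of the per-pixel Hessian, γ-normalized
by σ². Bright thin processes respond strongly; flat regions and the
interiors of blobs much larger than the scale do not. Scale 4 for
microglial processes, 2.0 for astrocyte ramifications.

**Astrocytes** follow a seven-stage chain: white top-hat of GFAP with a
50-px disc (line-structure enhancement); primary objects 10–300 px;
merge of objects whose boundary distance is ≤ 10 px into their largest
neighbor (the merge radius is a free parameter; 10 px is the default);
tubeness at σ = 2.0; secondary objects grown from the merged
primaries by seeded propagation (geodesic cost blending spatial distance
and intensity difference, λ = 0.05) inside an adaptive mask — a robust
background threshold computed per 256-px block and bilinearly blended;
a final ramification merge; and a nucleus gate keeping only
GFAP-positive objects overlapping at least one DAPI nucleus (an
astrocyte without a nucleus in the section plane is not counted).

**Phospho-tau** objects are primary objects of the AT8 channel,
diameters 1–80 px, robust background with k = 20, no nucleus
requirement. Objects with area < 900 px² are threads; 900 ≤ area <
10,000 are tangles; ≥ 10,000 are unclassified (the literal text leaves
900 itself unassigned; it is assigned to tangles here, and both
boundary conventions are tested). "Area occupied" — the tau burden
readout — sums the area of *all* pTau objects, unclassified included.

## Morphometry

Compactness is the mean squared distance of an object's pixels from its
unweighted centroid divided by its area, normalized so a filled circle
scores 1: C = 2π·MSD/A. The 2π factor is forced by the circle anchor —
for a disk of radius R, MSD = R²/2 and A = πR², so the bare ratio is
1/(2π); the verbal formula alone would contradict the anchor, which is
why the normalization is stated prominently. A single pixel scores 0
(pixel-center convention); ramified shapes score above 1. Eccentricity
comes from the second central moments; the perimeter uses the classical
boundary-configuration weighted estimator (straight 1, diagonal √2,
corner (1+√2)/2); equivalent diameter is 2·√(A/π). All features are
checked against per-pixel brute-force oracles.

## Phenotyping

A cell is **marker-high** (used for CD74) when its mean intensity is
strictly above the mean + 2 SD of all microglia of the *same donor
section* — never pooled across donors; the flags are invariant to affine
intensity rescaling. A microglia is **rounded** when its compactness is
≤ 2.5 (inclusive). Section aggregation divides counts by the gray-matter
area of the accepted tiles (4X gray pixels × pixel area); percentage
fields are missing, not zero, when their denominator is empty; the
rounded percentages within the CD74-high and CD74-low subsets partition
the microglia.

## Association statistics

`linear_association` is OLS with a two-sided t-test on the predictor of
interest, adjusting for the configured covariates (age, sex,
dichotomized background staining level, post-mortem interval where
available); rows with missing values are dropped listwise, rank
deficiency is an error, and no multiple-testing correction is applied by
default. The dichotomized background level is an input covariate; its
derivation is supplied by the user. `paired_wilcoxon` is the signed-rank
test on nonzero differences: exact null for ≤ 25 untied informative
pairs, tie-corrected normal approximation with continuity correction
otherwise. `pearson_r` is the standard product-moment correlation with
test. `group_slopes` fits, per group, score ~ time with subject-level
random intercepts and slopes by REML; on non-convergence (or a
degenerate design) it falls back to averaging per-subject OLS slopes and
labels the result accordingly.

## The synthetic-data generator

There is no generative model of immunofluorescence in the source
material, so every distribution here is an invented, documented
stand-in; all parameters are surfaced in `sim_tile_params()` /
`sim_section_params()` / `generate_cohort()`, and one seed governs all
randomness (fixed seed ⇒ byte-identical output).

Defaults emulate gray matter at 48 microglia per mm² — a realistic
median for thin sections of human DLPFC gray matter — with 500 other
nuclei and 60 astrocytes per mm², so microglia are a realistic ~8–9%
minority of nuclei (the mean+2SD IBA1 gate presupposes a
minority population). Object counts are Poisson draws at these
densities; the ground-truth table records what was actually rendered, so
recovery is always scored against realized truth. Nuclei are ellipses
(other nuclei 24–38 px, microglia nuclei 18–26 px equivalent diameter)
placed with radius-aware minimum separations — nuclei in a 6 µm section
do not interpenetrate. Microglia render as a perinuclear IBA1 soma
(radius 8–14 px, always wrapping the nucleus, as IBA1 cytoplasm does)
with 2–6 random-walk processes of width 1–2 px and length 20–60 px whose
intensity is varicose (beads-on-a-string, as real IBA1 staining is) —
this matters: perfectly uniform processes would give the intensity
declump no saddles to split at. A configurable fraction (default 5%) of
microglia are ameboid (no processes). Astrocytes are GFAP stars over
their own nuclei; pTau renders as curvilinear threads and lumpy blob
tangles. CD74 staining paints a per-cell level over the cell footprint:
CD74-low levels are Gaussian around 0.10, the planted high component
(default fraction 0.05) around 0.80 — an ~8-fold contrast, at the
conservative end of what activated antigen-presenting microglia show.
The contrast must be this large *as measured*: the per-object mean is
taken over the segmenter's fragment masks, which are several times
wider than the 1–2 px painted process cores, so a ramified cell's
measured mean is flux-diluted ~3–5×, and the planted "well beyond
+3 SD" separation has to survive that dilution. CD74-high cells are
additionally rendered ameboid — the rounded, process-retracted
morphology that characterizes these activated cells — which removes
the morphology-dependent dilution from the high population and is the
phenotype the cells are reported to have. The CD74 channel uses a wider
PSF (σ = 2; diffuse cytoplasmic stain imaged in the far red) than the
other channels (σ = 0.7); all channels get a smooth background
gradient and Gaussian read noise (σ = 0.008). Planted per-tile defects:
`empty` (no cells), `blur` (σ = 4), `debris` (bright blobs across all
channels).

Sections add a 4X brightfield/DAPI pair: an elliptical tissue blob with
a white-matter band placed so the bottom tile row straddles the
gray/white boundary at ~50% (exercising the 95% gate) while the upper
rows are fully gray.

What passing on this generator shows — and what it does not: the
pipeline's thresholds, declumping, linking and classifiers recover known
objects under noise, blur, gradients and crowding typical of the
configured densities. The generator does not emulate autofluorescence,
lipofuscin, uneven illumination, section folds, staining batch effects
or true microglial morphology variation, so passing here does not
certify performance on real slides; the statistical rules
(mean+2SD, ≤2.5, 95% gate) are exact by construction regardless.

## Validation sizes and numerical choices

The validation suite uses 510-px tiles (0.0277 mm²) in 2×3-tile
sections; parameter-recovery runs use 20 seed-sections and score pooled
recall, precision, density and CD74-high percentage against realized
truth. Because a desk-scale section holds only ~5 microglia — far too
few for a mean+2SD tail classifier — the CD74-high recovery readout
pools the seed-sections into one sample; they are i.i.d. draws of one
staining model, so this is statistically a single sample. Per-donor
behavior of the classifier is validated separately on perfect masks at
n = 2,000. Cell matching uses nucleus centroids within 10 px.

Other numerical choices: 256 Otsu bins; 5%/5% robust-background trims;
watershed tolerances (1 px shape, 0.02 relative intensity); 32 radial
frequency bins over 5–45% of Nyquist; adaptive-threshold blocks of 256
px; propagation λ = 0.05; merge radius 10 px; all exposed in
`seg_params()` and `qc_policy()`.

## Known limitations

* 2-D only; no 3-D or machine-learned segmentation, no illumination
  correction or stitching (done upstream by the scanner software).
* The assembled-microglia morphology depends on fragment recovery;
  heavily blurred or dim processes reduce compactness toward the soma
  value, biasing cells toward "rounded".
* The marker-high rule needs a population (≥ 3 objects; realistically
  hundreds) and assumes a unimodal low-expressing majority.
* White-matter microglia and cortical layers are out of scope; analysis
  is gray matter only.

## A worked end-to-end example

```{r example, eval = FALSE}
library(gliaquant)
r <- evaluate_recovery(seed = 11)
r[c("truth_density", "est_density", "recall", "precision")]
# full directory-tree run with manifest and CSV outputs:
cfg <- run_config(seed = 11, simulate = list(grid = c(2L, 3L)))
run_pipeline(cfg, "gliaquant_run")
```
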