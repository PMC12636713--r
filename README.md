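# gliaquant

Automated segmentation and quantification of microglia, astrocytes and
phospho-tau in whole-slide immunofluorescence scans of human cortex.

## What it does, and for whom

Neuropathology groups profiling post-mortem cortex stain sections with
DAPI (nuclei), IBA1 (microglia), GFAP (astrocytes), AT8 (phospho-tau)
and a marker of interest such as CD74 (MHC class II invariant chain),
scan the whole section at 20X (0.325 µm/px) plus a 4X brightfield/DAPI
overview, and want per-donor, per-cell quantities without manual
counting. `gliaquant` provides that pipeline end to end:

1. **Tissue and gray matter** from the 4X pair: tissue is the
   intersection of the Otsu-binarized brightfield (dark class) and DAPI
   (bright class); a second Otsu cut within tissue labels the darker
   class gray matter. A 20X tile is analyzed only if > 95% of its
   footprint is gray matter.
2. **Tile QC**: empty, blurry (power log-log slope of the spectrum) and
   debris-contaminated tiles are flagged by an explicit percentile +
   outlier-guard policy.
3. **Segmentation** (CellProfiler-style, reimplemented): nuclei
   (18–80 px, robust background threshold, watershed shape declumping);
   microglia as nuclei with equivalent diameter < 40 px and IBA1
   intensity > mean + 2 SD of all nuclei, assembled with
   tubeness-enhanced IBA1 cytoplasm fragments linked within 60 px;
   astrocytes via line-structure enhancement, seeded propagation and a
   DAPI gate; pTau objects (1–80 px, 20-SD robust background) split
   into threads (area < 900 px²) and tangles (900–10,000 px²).
4. **Morphometry and phenotyping**: per-object area, perimeter,
   eccentricity, marker intensities, and compactness

   C = 2π · MSD / A,

   the mean squared pixel distance from the centroid over the area,
   normalized so a filled circle scores 1. "Rounded" (ameboid,
   activated-morphology) microglia have C ≤ 2.5; "CD74-high" microglia
   exceed the mean + 2 SD of CD74 intensity of all microglia in the
   same donor section. Densities are per mm² of gray matter.
5. **Association statistics**: covariate-adjusted linear models, paired
   Wilcoxon signed-rank tests, Pearson correlations and mixed-model
   (random intercept + slope) group cognitive slopes.

A seeded synthetic-data generator (five-channel tiles, 4X section
pairs, donor cohorts, full ground truth) makes every stage testable
without microscope data.

## Worked example

Generate a synthetic section at the default conditions (planted density
48 microglia/mm², 5% CD74-high), run the pipeline on it, and score the
result against the generator's ground truth:

```r
library(gliaquant)
r <- evaluate_recovery(seed = 2)
str(r[c("truth_density", "est_density", "recall", "precision",
        "gray_area_mm2", "n_detected")])
#> List of 6
#>  $ truth_density: num 54.6
#>  $ est_density  : num 54.6
#>  $ recall       : num 1
#>  $ precision    : num 1
#>  $ gray_area_mm2: num 0.11
#>  $ n_detected   : int 6
```

The section's four accepted tiles cover 0.11 mm² of gray matter; all 6
planted microglia were recovered (recall and precision 1.0), so the
estimated density equals the realized planted density, 54.6 cells/mm²
(a Poisson draw around the configured 48/mm²).

A full directory-tree run — config, 16-bit TIFF masks and label maps,
QC report, object CSVs, section summary and manifest:

```r
cfg <- run_config(seed = 21, simulate = list(grid = c(2L, 2L)))
run_pipeline(cfg, "gliaquant_run")
```

Classifier rules are plain functions:

```r
classify_marker_high(c(2, 3, 4, 5, 6, 30))   # mean + 2 SD rule
#> [1] FALSE FALSE FALSE FALSE FALSE  TRUE
#> attr(,"threshold")
#> [1] 29.74984
classify_rounded(c(1.0, 2.5, 2.51))           # compactness <= 2.5
#> [1]  TRUE  TRUE FALSE
```

A thin command-line front end over the same functions is installed at
`inst/cli/gliaquant.R` (`simulate`, `detect-tissue`, `qc`, `segment`,
`run-all` subcommands, each taking `--config`, `--seed`, `--out`).

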