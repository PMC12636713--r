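Package: gliaquant
Title: Automated Segmentation and Quantification of Glia and Phospho-Tau in
    Whole-Slide Immunofluorescence Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An automated image-analysis pipeline for multi-channel
    immunofluorescence scans of human cortex. Delineates gray matter from
    low-magnification brightfield/DAPI pairs, quality-controls 20X image
    tiles, segments nuclei, microglia (two-step nucleus + cytoplasm-fragment
    assembly), astrocytes and phospho-tau deposits, measures per-object
    morphometry including a circle-anchored compactness score, classifies
    marker-high (mean + 2 SD) and morphologically rounded cells, aggregates
    per-donor section summaries, and fits the downstream association
    statistics (covariate-adjusted linear models, paired Wilcoxon signed-rank
    tests, Pearson correlations, mixed-model cognitive slopes). Ships a
    seeded synthetic-data generator producing five-channel tiles, 4X
    whole-slide pairs and donor cohorts with ground truth so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    yaml,
    jsonlite,
    lme4,
    pracma,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
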