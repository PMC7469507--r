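Package: adipotrace
Title: Semi-Automated Adipocyte Morphometry for H&E Histology Images
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measures adipocyte cross-sectional areas in H&E-stained adipose
    tissue images with three complementary modes: a semi-automated trace mode
    in which a single seed click inside a cell drives a flood fill and
    interior boundary trace over a binarized image, manual polygon hand
    tracing, and ellipse approximation (pi*A*B). Provides the
    levels/threshold/despeckle image transform that precedes tracing, micron
    calibration of pixel areas, size-distribution histograms, repeatability
    summaries and pairwise method-concordance regression, plus a synthetic
    adipose-histology simulator with per-cell ground truth for validating the
    whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    png,
    tiff,
    jpeg
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
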