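Package: hcscreen
Title: Simulation and Analysis of Imaging-Based High-Content RNAi Screens
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for imaging-based high-throughput RNAi screens that use
    per-nucleus fluorescence as the readout. Generates fully synthetic
    screens with known ground truth (384-well plate layouts with library
    and control wells, additive well-value models with plate row/column
    artifacts, rendered two-channel well images and metaphase-spread
    images), quantifies nuclear fluorescence from images (DAPI-based
    segmentation, roundness and border filtering, per-well mean of
    per-nucleus means), and implements the screen statistics chain:
    per-plate B-score normalization by two-way median polish with robust
    variance adjustment, per-replicate robust Z-scores, replicate
    averaging, gene-level median aggregation over sibling siRNAs, ranking
    and hit calling. Also provides box-based spot intensity quantification
    with cytoplasmic background correction and the associated two-sample
    t-test and one-way ANOVA with Tukey post hoc comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    EBImage,
    tiff,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
biocViews: CellBasedAssays, Software, Visualization, Preprocessing
Config/testthat/edition: 3
RoxygenNote: 7.3.3
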