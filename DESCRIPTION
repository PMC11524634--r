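Package: cfzkit
Title: Design, Simulation, and Image Analysis of Cell-Free Zone Migration Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for automated wound-healing (cell-free zone) assays in
    cell monolayers. Provides declarative wound-shape design with tip
    toolpath planning and rasterized ground-truth masks, multi-well plate
    calibration by bilinear interpolation of four corner wells, an
    agent-based simulator of a nuclear-stained monolayer closing a wound by
    migration and proliferation, and a full image-analysis pipeline:
    preprocessing (grayscale flattening, spatial and intensity rescaling,
    median filtering, contrast-limited adaptive histogram equalization),
    nuclear segmentation (multi-scale Laplacian-of-Gaussian detection with
    marker-controlled watershed), isolated-detection filtering, density-based
    wound masks with contour-derived wound edges, width profiles and closure
    curves, and Kalman-filter single-cell tracking with global assignment
    and lineage linking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    parallel,
    jsonlite,
    clue,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'cfzkit-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'imagestack.R'
    'io.R'
    'metrics.R'
    'pipeline.R'
    'plate.R'
    'preprocess.R'
    'segment.R'
    'simulate.R'
    'track.R'
    'utils.R'
    'wound-design.R'
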