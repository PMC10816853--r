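Package: asploss
Title: Adaptive Sample-Level Prioritizing Losses for Mass Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the Adaptive Sample-level Prioritizing (ASP) family of
    loss functions for binary mass segmentation in mammography: ratio-driven
    hybrids (quantile, value and cluster based grouping of mass-to-image
    ratios, plus a learned weighting subnetwork), a density-driven hybrid that
    scales region-level terms (structural similarity and regional mutual
    information) by the ACR breast-density category, and adaptive focal
    variants that pick the focusing parameter per sample. Ships the pixel- and
    region-level constituent losses with analytic gradients, segmentation
    metrics (Dice similarity, relative area difference, sensitivity,
    accuracy), a synthetic mammogram-phantom generator with controlled mass
    ratio and density category, and a CPU-scale encoder-decoder training
    harness for end-to-end exercise of every loss.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    tools,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    png,
    tiff
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
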