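Package: hifquant
Title: Human-Interpretable Image Features from Tissue and Cell Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the tumor microenvironment from dense tissue-type label
    rasters and cell-type point tables. Computes a catalog of 607 named
    human-interpretable image features (HIFs) spanning tissue areas and
    multiplicities, connected-component morphology (marching-squares perimeter,
    fractal dimension, lacunarity, solidity), and cell-level spatial statistics
    (densities, 80-micron proximity features, Birch cluster features). Provides
    patient-level aggregation, pan-cohort Z-scoring, correlation-based HIF
    clustering, association testing against molecular signatures with the
    Empirical Brown's method, Gaussian-mixture binarization of continuous
    outcomes, tissue-source-site hold-out splits, and a logistic sparse group
    lasso with nested cross-validation and ensembling. A synthetic scene and
    cohort generator with known ground truth supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    png,
    mclust,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml,
    optparse
Config/testthat/edition: 3
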