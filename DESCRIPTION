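Package: envinet
Title: Multi-Level Omics Network Analysis for Environmentally Sampled
    Non-Model Organisms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for integrating transcriptomic, metabolomic
    and morphometric data from field-sampled organisms: microarray and NMR
    preprocessing (flooring, quantile normalisation, coefficient-of-variation
    de-noising, probabilistic-PCA imputation, empirical-Bayes batch
    correction, clone-cluster collapse, spectral binning), site-wise
    differential expression with Benjamini-Hochberg control, directional
    chemical-signature inference from chemical-gene interaction tables via
    EASE scores, mutual-information network inference with data-processing-
    inequality pruning, hub-neighbourhood module extraction with overlap-index
    module graphs, genetic-algorithm feature selection scoring per-module
    class predictivity, and module-level integration against laboratory
    exposure signatures. Ships a synthetic-data generator with planted ground
    truth so the whole pipeline is testable without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    class,
    cluster,
    jsonlite
Suggests:
    limma,
    sva,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
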