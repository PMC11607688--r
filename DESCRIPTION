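Package: gastroquant
Title: Quantitative Image and Single-Cell Analysis of Gastruloid Symmetry Breaking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying anteroposterior (AP) symmetry breaking in
    gastruloids from wide-field microscopy and single-cell data. Provides
    brightfield segmentation via a multi-scale pixel-feature bank and a
    three-class logistic-regression pixel classifier with a seeded-watershed
    alternative; distance-transform midline extraction, computational
    straightening and second-moment eccentricity; oriented and normalized AP
    fluorescence-intensity profiles, replicate averages and kymographs;
    coarse-grained tissue-flow measurement by pyramidal Lucas-Kanade optical
    flow with rigid pre-registration and temporal averaging; and single-cell
    utilities covering QC filtering presets, marker-gene gating,
    nearest-neighbour label transfer in PC space with transfer-quality
    statistics, cluster-correlation matrices and cluster-average differential
    expression. A synthetic-data generator produces images, time-lapses, cell
    tables and paired embeddings with known ground truth so that every stage
    is benchmarked without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    glmnet,
    igraph,
    EBImage,
    tiff,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr
Config/testthat/edition: 3
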