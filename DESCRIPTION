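Package: mihcflow
Title: Sequential Multiplex Immunohistochemistry Image Analysis and
    Single-Cell Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for sequential chromogenic multiplex
    immunohistochemistry (mIHC): co-registration of per-round brightfield
    images by feature matching and robust similarity fitting, AEC/hematoxylin
    optical-density stain deconvolution, watershed nuclear segmentation and
    single-cell marker quantification, config-driven hierarchical gating with
    spatial (epithelium + stromal margin) gates, automated cell phenotyping by
    landmark sparse subspace clustering with spectral partitioning, and
    k-nearest-neighbour permutation tests for phenotype neighbourhood
    enrichment, together with stage-wise nonparametric group comparisons.
    Ships a synthetic-tissue generator with full ground truth so every stage
    of the pipeline is testable without patient images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    rlang,
    ggplot2,
    generics,
    readr,
    stats,
    utils,
    EBImage,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    glmnet,
    optparse
Config/testthat/edition: 3
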