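Package: decomap
Title: Cell-Type and Brain-Region Decomposition of Bulk RNA-Seq Against a
    Single-Cell Reference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative analysis of bulk RNA-seq cohorts against a labeled
    single-cell reference for the developing brain. Provides preferential
    expression measure (PEM) normalization of cell-type expression profiles,
    Kolmogorov-Smirnov enrichment of differentially expressed gene sets per
    cell type, signature-based cell-fraction deconvolution by non-negative
    least squares with group comparison, and gene-set spatial scoring over
    voxelized in situ hybridization expression volumes. Ships a negative
    binomial synthetic-data generator that emulates a two-batch, mixed-sex
    fetal-brain cohort with cell-type-specific planted differential
    expression, so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
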