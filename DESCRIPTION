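Package: metabokit
Title: Metabolomics Feature-Table Preprocessing, Statistics and Reporting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scriptable pipeline for LC-MS metabolomics feature tables:
    ingestion of CSV/XLSX exports from peak-picking software, missing-value
    imputation (single-value and k-nearest-neighbour), pooled-QC RSD
    filtering, normalization (internal standard, linear baseline,
    probabilistic quotient, quantile), log10 transformation and feature
    scaling; per-feature univariate tests with Benjamini-Hochberg FDR
    control, fold-change analysis, PCA, PLS-DA (NIPALS) with VIP scores and
    cross-validated Q2, hierarchical clustering and correlation-threshold
    networks; a self-contained HTML report generator; and a synthetic-data
    generator with known ground truth so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    glue,
    readr,
    readxl,
    ggplot2,
    generics,
    ragg,
    igraph,
    ape,
    jsonlite,
    digest,
    yaml,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    xml2,
    withr
Config/testthat/edition: 3
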