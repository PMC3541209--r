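Package: myoinfil
Title: Leukocyte Infiltration Indexing and Mixture-Adjusted Expression
    Analysis for Inflamed Tissue Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Quantifies leukocyte infiltration in bulk tissue expression
    profiles via an invasion-model leukocyte index: differential
    expression against normal controls, bootstrap multi-algorithm
    consensus clustering with membership robustness, median-fold-change
    gene-signature scoring, and adjustment of the expression matrix by
    the resulting per-sample index to separate infiltration-driven from
    tissue-intrinsic transcriptional change.  Includes a linear
    cell-type-mixture cohort simulator with known ground truth, the
    associated correlation and regression analyses (principal-component,
    histology-grade and mRNA-miRNA anti-correlation screens), and an
    end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    limma,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
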