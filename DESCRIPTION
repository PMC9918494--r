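Package: immureg
Title: Immune Regulatory Network Inference from Multi-Omics Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers transcription-factor regulation of immune-related genes
    from matched RNA-seq, ATAC-seq, copy-number and clinical data, at two
    complementary levels: a single-sample framework that links accessible
    chromatin peaks near a gene's transcription start site to candidate
    transcription factors and calls signed regulatory edges per patient, and
    a population framework that selects regulators per tumour subtype by
    L0-penalized (best-subset) regression with cross-validated penalty
    choice. Also provides non-negative matrix factorization consensus
    clustering with cophenetic rank selection for immune-subtype discovery,
    a stimulatory/inhibitory signature-gene filter, per-cluster
    copy-number/expression correlation, and an L1-penalized Cox risk score
    with Kaplan-Meier, log-rank and time-dependent AUC evaluation. A
    synthetic multi-omics cohort generator with planted ground truth makes
    the full pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    cluster,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    igraph,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
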