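Package: gsreg
Title: Gene Set Regularity Analysis of Transcriptome Functionomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Rank-based gene set regularity (GSR) analysis for multi-platform
    transcriptome cohorts. Encodes each gene set as within-sample pairwise
    expression orderings, derives a majority rank template from control
    samples, and scores every sample by the fraction of pair orderings that
    match the template, yielding a samples-by-gene-sets functionome of GSR
    indices in [0, 1]. Downstream stages call dysregulated gene sets with
    Mann-Whitney tests under Benjamini-Hochberg false-discovery control,
    cluster significant Gene Ontology terms in the ontology graph and rank
    clusters by a cluster weight index, classify functionome patterns with a
    support vector machine under repeated stratified cross-validation, rank
    canonical pathways by p-value, and nominate representative genes by
    repetition across category gene sets. A seeded synthetic-cohort generator
    with planted order dysregulation makes the whole pipeline testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    kernlab,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
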