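Package: sigscape
Title: Mutational Signature Catalogs, Extraction and Interaction Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for somatic mutational signature analysis of cancer
    whole genomes. Builds SBS96, DBS78 and ID83 mutation catalogs from
    simple somatic mutation (SSM) records, extracts de novo signatures by
    Kullback-Leibler non-negative matrix factorization with bootstrap
    stability and silhouette-based rank selection, refits exposures
    against a reference signature set by non-negative least squares,
    derives per-sample signature profiles (presence, dominant signatures,
    etiology groups, mutation burden), tests pairwise signature
    co-occurrence and mutual exclusivity with the exact hypergeometric
    test, and compares stratified cohorts (tumor grade, homologous
    recombination deficiency status) with exact and rank-based tests.
    Includes a fully specified synthetic-cohort generator with known
    ground truth for every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
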