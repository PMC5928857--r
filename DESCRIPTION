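Package: timeatlas
Title: Tumor Immune Microenvironment Subtyping, Neoantigen Abundance and
    Outcome Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for immunoproteogenomic profiling of
    solid tumors, developed around malignant pleural mesothelioma. Clusters
    single-cell mass-cytometry events into annotated subpopulation nodes,
    builds landmark-anchored similarity graphs, and discovers two tumor
    immune microenvironment (TiME) subtypes by unsupervised clustering.
    Quantifies mass-spectrometry-detected mutant neopeptides (AUC and
    fraction-of-total normalization), tiers candidate MHC-I/II binders from
    percentile ranks against patient HLA types, derives a dual-level
    (mRNA and protein) discriminatory gene signature with a nearest-centroid
    classifier, and associates subtype calls with survival and
    immunotherapy response. Ships a synthetic-cohort generator with planted
    ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    seqinr,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    mclust,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
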