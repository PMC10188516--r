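Package: pwastox
Title: Pesticide-Wide Association Screening and Dopaminergic Neurotoxicity
    Assay Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, simulation-backed implementation of a record-based
    pesticide epidemiology and neurotoxicity screening workflow. Provides
    GIS buffer-based ambient exposure assessment from agricultural
    application records (acreage-weighted pounds per acre within a 500 m
    buffer, exposure-window averaging, log1p standardization), a
    pesticide-wide association study (per-stratum unconditional logistic
    regression pooled by fixed-effects inverse-variance meta-analysis with
    Benjamini-Hochberg false discovery rate control), Fisher-exact
    overrepresentation analysis of pesticide groups, co-exposure
    correlation, network and cluster analysis, and the statistics of a
    high-content dopaminergic-neuron toxicity screen (object filtering,
    control-referenced intensity thresholds, 3-SD toxicity calls, Z-prime,
    dose summaries, combinatorial co-exposure tests, and mito-stress
    parameter extraction from oxygen-consumption traces). A synthetic-data
    generator with recorded ground truth makes every stage testable without
    access to confidential cohort data.
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
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
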