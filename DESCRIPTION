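Package: mirpronet
Title: Integrative miRNA-Proteome Differential Expression and Regulatory
    Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrating small-RNA and quantitative-proteome
    profiles from a two-condition design into a miRNA-protein regulatory
    network, as used to study eyestalk-ablation induced ovarian maturation
    in decapod crustaceans. Provides TPM normalization and a conditional
    exact binomial test for pooled-library miRNA differential expression,
    fold-change and replicate t-test calling for iTRAQ-style protein
    tables, a seed-weighted G:U-aware local alignment scanner for miRNA
    target sites in 3'UTRs, inverse-correlation network construction, and
    the downstream validation statistics (dual-luciferase Tukey HSD,
    comparative-CT relative expression, exact-permutation Spearman
    correlation), together with a seeded synthetic-data generator that
    emulates the study design for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
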