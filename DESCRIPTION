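Package: necmgs
Title: Metagenomic Species Profiling and Diversity Analysis for a Synthetic Preterm NEC Cohort
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested reimplementation of a shotgun-metagenomics analysis
    pipeline for gut microbiota of preterm children with a history of
    necrotizing enterocolitis (NEC). Provides a synthetic cohort and read
    simulator with known ground truth; high-quality non-host (HQNH) read-pair
    filtering; read-to-gene-catalog classification and unique-pair counting;
    metagenomic species (MGS) signature-gene abundance profiling with
    detection filtering, effective-length normalization and rarefaction;
    rank-specific consensus taxonomy from blast-like hit tables; alpha and
    beta diversity (Shannon, Simpson dominance, richness, Berger-Parker,
    Lorenz/Gini, Bray-Curtis, rarefaction curves, PCA); nonparametric group
    statistics with effect sizes and Bonferroni adjustment; and
    interval-based association-rule mining of clinical predictors of alpha
    diversity scored by support and confidence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    withr
Config/testthat/edition: 3
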