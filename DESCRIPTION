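Package: phylosym
Title: Phylosymbiosis Statistics for Coupled Microbiome and Metabolome
    Feature Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies how strongly host-associated chemical and microbial
    profiles mirror each other and the host phylogeny ("phylosymbiosis").
    Provides feature-table preprocessing for untargeted metabolomics
    (internal-standard normalization, noise floors, balance-score and
    background filtering), Bray-Curtis/Jaccard dissimilarities and principal
    coordinates, sequential (Type I) permutational multivariate ANOVA with
    dispersion diagnostics and subset-robustness resampling, Mantel tests,
    Ward dendrogram to phylogeny congruence via Baker's Gamma with a
    label-shuffle permutation null, indicator-value (IndVal) differential
    feature discovery seeded by PCA loadings, and a fully seeded synthetic
    generator of coupled microbiome/metabolome/function tables with
    controllable phylosymbiotic signal for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
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
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
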