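Package: twinherit
Title: Twin-Based Heritability, Genetic Correlation, and Latent
    Brain-Behavior Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantitative-genetic and multivariate analysis of twin cohorts:
    maximum-likelihood variance decomposition on extended-twin pedigrees
    (heritability with boundary likelihood-ratio tests), bivariate polygenic
    models yielding genetic and environmental correlations, covariate-adjusted
    Spearman association mapping across cortical parcels with false-discovery
    control, and partial-least-squares latent brain-behavior analysis with
    permutation and bootstrap inference. Includes a synthetic twin-cohort
    generator with configurable heritabilities, trait correlations, covariate
    effects, and planted low-rank brain-behavior structure, so the full
    pipeline is testable without access-restricted data.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
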