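Package: npbat
Title: Phenotype-Conditioned Score Tests for Population-Based Genetic
    Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Semi-parametric single-marker association tests for
    population-based designs that condition on the phenotype and treat the
    genotype as the random variable, so that validity does not depend on a
    phenotypic model.  Supports efficient trait codings for binary,
    continuous and covariate-adjusted phenotypes, ascertainment-aware
    variance corrections for secondary phenotypes observed only in cases of
    a case-control study, a multivariate extension with permutation
    significance, Monte-Carlo power and type-I-error studies with
    truncated-normal secondary phenotypes, and PLINK-style text file input
    with a small command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
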