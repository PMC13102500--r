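Package: cortmodels
Title: Gamma-Likelihood Models for Corticosterone Stress Responses in Wild Birds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing plasma corticosterone (CORT) measured in
    wild birds exposed to different capture and control methods. Implements
    gamma generalized linear models comparing CORT across treatment groups
    with likelihood-ratio tests and Bonferroni-adjusted pairwise contrasts;
    maximum-likelihood fitting of nonlinear (logistic and quadratic) gamma
    mean models for the CORT time course after capture; AICc-based model
    comparison with Akaike weights, deviance pseudo-R2, and a parsimony
    selection rule; a sex-varying logistic model family; delta-method and
    parametric-bootstrap confidence bands for predicted curves; and a seeded
    synthetic-data generator that reproduces the sampling design of a
    shooting / baseline / trapping-confinement study so every stage of the
    pipeline is testable without access to raw field data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    emmeans,
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
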