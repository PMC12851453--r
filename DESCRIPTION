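Package: cultnet
Title: Cultural Transmission Analysis in Family and Peer Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how attitudes and behaviours are shared
    within small social networks built around a focal individual (a student
    plus parents, grandparents and friends). Provides a long-format network
    table data model with filtering, imputation, relationship averaging and
    trait dichotomisation; a Monte-Carlo permutation "Resemblance" z-score
    for dyadic Pearson correlations and a significance-graded resemblance
    graph; classification of networks into cultural parental types with
    additive transmission coefficients and bootstrap confidence intervals;
    maximum-likelihood and least-squares grid estimation of Vertical,
    Horizontal and Other transmission biases; and a seeded synthetic
    network generator so every stage of the pipeline can be exercised and
    calibrated without survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
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
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
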