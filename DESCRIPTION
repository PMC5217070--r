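Package: genegroups
Title: Genetic Group Animal Models for Pedigrees with Unknown Parents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative genetic animal models for pedigreed populations in
    which many individuals have unknown parents. Builds the additive
    relationship matrix A, its Henderson factors T and D, the sparse inverse
    A-inverse, the genetic-group contribution matrix Q and the group-augmented
    inverse A-star (with hard or fuzzy phantom-parent classification), fits
    basic, explicit-group and implicit-group animal models by sparse BLUP with
    profile REML variance estimation, and simulates pedigreed populations with
    immigrant gene flow to demonstrate and correct the bias that genetically
    non-random unknown parents induce in breeding-value prediction and
    additive-variance estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
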