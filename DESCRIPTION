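Package: ctldyn
Title: Tumor-Immune Dynamics of Fast and Slow CTL Killing Under Checkpoint Blockade
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates and analyses a three-compartment ordinary differential
    equation model of tumor-immune dynamics in which cytotoxic T lymphocytes
    kill high- and low-antigen tumor cells through a fast (perforin/granzyme)
    and a slow (FasL) mechanism, under an active or blocked PD-1/PD-L1 immune
    checkpoint. Provides an adaptive Dormand-Prince integrator with clinical
    detection-limit event handling, steady-state and bistability analysis,
    (p1, p2) response grids with checkpoint-blockade reduction contours, a
    Latin hypercube virtual cohort of mice with clinical outcome
    classification, and partial-rank-correlation global sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    numDeriv,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
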