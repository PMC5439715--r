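Package: regrowr
Title: Post-Irradiation Tumor Population Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of glioblastoma cell population dynamics after
    high-dose ionizing radiation: linear-quadratic clonogenic survival
    fitting, exponential growth-rate and population-doubling kinetics, a
    stochastic lattice cellular-automaton model of tumor regrowth with a
    non-proliferative metabolically active (NPMA) compartment that
    discriminates local from host-mediated (global) growth inhibition, a
    multi-group ANOVA differential-expression screen with Holm correction,
    2^-ddCt relative quantification for qPCR, and dye-dilution division
    tracking by constrained Gaussian-mixture deconvolution. Ships synthetic
    data generators with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    tools,
    withr,
    yaml,
    jsonlite,
    limma,
    readr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    broom
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
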