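Package: ecoresist
Title: Frequency-Dependent Ecological Models of Preexisting Drug Resistance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic and analytical models for the fate of costly
    resistance-conferring mutants under frequency-dependent ecological
    interactions with their ancestor. Provides a generalized Moran
    birth-death process with exact absorption probabilities and
    extinction-time distributions, a lineage-tracking Wright-Fisher
    simulator in which every mutant carries its own intrinsic and
    ecological fitness drawn from configurable distributions (DFE/DEE),
    closed-form approximations for mean extinction times, expected mutant
    numbers (including a Lambert-W mutation-selection balance), stationary
    mutant-fitness distributions and regime classification, and estimation
    of frequency-dependent fitness from two-channel coculture game-assay
    timecourses.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
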