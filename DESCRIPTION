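Package: songgaps
Title: Coupling of Syllable Sequencing and Timing in Birdsong
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how syllable sequencing relates to syllable
    timing in Bengalese finch song. Provides amplitude-threshold syllable
    segmentation of song waveforms, Markov transition models of song syntax
    with likelihood-ratio tests for history dependence and branch-point
    classification, inter-syllable gap measurement with cross-recording
    amplitude normalisation, and linear mixed-effects analyses (REML with
    bird and sequence-within-bird random intercepts) of the coupling between
    transition probabilities and silent-gap durations, including paired
    condition (age- or social-context-dependent) change analyses with
    chi-square transition categorisation and Tukey HSD contrasts. A synthetic
    song generator with full ground truth supports validation and power
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
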