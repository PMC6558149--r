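Package: ordlag
Title: Multi-Lag Ordinal-Pattern Entropy Analysis of EEG Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Symbolic (ordinal-pattern) entropy analysis of multichannel EEG
    across embedding delays, for discriminating calm from distressed affective
    states. Implements delayed amplitude-aware permutation entropy, Renyi
    permutation entropy and permutation min-entropy; multi-lag entropy-curve
    features (slopes, areas, arc length); EEG preprocessing with independent
    component artifact scoring and noisy-channel interpolation; statistical
    testing and stratified cross-validated classification with sequential
    forward feature selection; and a seeded synthetic EEG generator so the
    full pipeline can be exercised and validated without any recording
    database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    signal,
    ica,
    e1071,
    MASS,
    rpart,
    car
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
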