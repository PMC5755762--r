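Package: sleepchain
Title: Four-State Markov Modelling of Rodent Sleep-Wake Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing rodent sleep-wake architecture from
    EEG/EMG recordings scored in 5-second epochs. Implements automated
    three-state sleep staging (band-limited RMS z-scores, ratio indices,
    threshold seeding and a two-pass K-means refinement), bout extraction
    with a brief/long wake split at 150 seconds, Kaplan-Meier
    bout-survival curves with log-rank comparisons, geometric-mixture
    bout-duration models, and discrete-time four-state Markov chain
    estimation stratified by dark and light phases. A synthetic-data
    generator simulates phase-switched Markov hypnograms and
    state-conditioned EEG/EMG signals so the whole pipeline can be
    exercised and validated without animal recordings.
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
    signal,
    stats,
    tibble,
    tidyr
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
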