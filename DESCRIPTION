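Package: betadapt
Title: Pre-Movement Beta Oscillations During Visuomotor Adaptation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis of sensorimotor beta-band (15-25 Hz)
    oscillations around visuomotor adaptation. Provides a synthetic-data
    generator for joystick rotation-adaptation sessions and cat prism
    reach sessions (state-space error-driven learner, 1/f background,
    amplitude-modulated beta rhythm with movement-related
    desynchronization), EEG/LFP preprocessing (Hjorth surface Laplacian,
    bipolar re-referencing, zero-phase Butterworth filter chain,
    event-locked windowing), Morlet wavelet time-frequency decomposition,
    per-trial pre-movement beta power extraction, and the inferential
    battery used on such data: Spearman kinematic correlations,
    trial-wise error regression, covariate-adjusted epoch contrasts with
    Bonferroni correction, and balanced bootstrap comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    car,
    knitr,
    rmarkdown
Config/testthat/edition: 3
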