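Package: epiprobe
Title: Probing Seizure Resilience and Neural Excitability with the Epileptor Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying seizure resilience and neural excitability as a
    critical transition. Implements a stochastic five-dimensional Epileptor
    neural-mass simulator with stimulation protocols, fixed-point and fold
    bifurcation analysis, active probing metrics (evoked-response line length,
    input-output curves, rheobase, time-to-seizure), passive critical-slowing
    signatures (line length, variance, skewness, autocorrelation half-width,
    spatial correlation), non-negative matrix factorization of multi-channel
    stimulation responses into responsive sub-networks, bootstrap effect-size
    estimation, and permutation-tested multinomial decoding of excitability
    levels from intracranial EEG. A synthetic multi-channel iEEG generator
    emulating mouse-like stimulation sessions makes the full pipeline testable
    without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
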