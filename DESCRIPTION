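Package: selfcaught
Title: Brain-Body Dynamics Around Self-Caught Mind-Wandering Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for multimodal (EEG, ECG, respiration)
    recordings collected with the self-caught mind-wandering paradigm, in
    which participants press a key whenever they notice their mind has
    wandered.  Provides attentional-state labeling around self-caught
    reports, respiratory phase detection with a resampled-null inhalation
    rate test, R-peak detection and state-labeled RR-interval metrics,
    heartbeat-evoked potential (HEP) epoching with regression-based
    baseline correction, Morlet wavelet time-frequency decomposition,
    whole-scalp cluster-based permutation tests, and a Bayesian dual-trend
    state-space change-point model fit by a bundled Metropolis-within-Gibbs
    sampler with marginalized discrete change point.  A seeded synthetic
    recording generator with known ground truth makes every stage testable
    without access to human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    zoo,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
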