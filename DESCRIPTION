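Package: snapfim
Title: Distortion-Corrected Inference and Experiment Design for Single-Cell
    Snapshot Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Solves chemical master equation models of stochastic gene
    expression by finite state projection, together with forward parameter
    sensitivities, and propagates both through probabilistic distortion
    operators that model measurement noise in single-cell snapshot
    experiments (lossy spot counting, false positives, integrated
    fluorescence intensity, spurious detections).  Provides
    distortion-corrected likelihoods, maximum-likelihood and
    Metropolis-Hastings inference, calibration of distortion operators from
    paired two-channel measurements with BIC model selection, Fisher
    information matrices for distorted observables, and D-optimal ranking of
    measurement-time designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
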