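Package: TrackStates
Title: Multi-State Diffusion Analysis of Noisy Single-Particle Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maximum-likelihood analysis of single-particle tracking data in
    which molecules switch between diffusive motion states (for example bound
    and freely diffusing membrane proteins) while observed positions carry
    Gaussian localization error. Implements an exact Gaussian recursion over
    hidden molecule positions combined with a sliding-window sum over hidden
    state sequences to evaluate track likelihoods, fits global model
    parameters (localization error, per-state diffusion lengths, transition
    rates, initial fractions) by Powell's method, annotates per-time-point
    state probabilities, refines molecule positions by forward-backward
    smoothing, and extracts probability-weighted state-duration histograms.
    Includes a ground-truthed Brownian-dynamics track simulator with
    fine-time Markov switching, localization noise, parameter heterogeneity,
    finite-field-of-view and confinement geometries, plus readers for CSV and
    TrackMate-style XML track exports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    Matrix,
    Rcpp,
    jsonlite,
    xml2
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
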