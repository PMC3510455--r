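Package: slidefret
Title: Simulation and Kinetic Analysis of Protein-Filament Sliding by Single-Molecule FRET
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying one-dimensional sliding of double-stranded DNA
    along a RecA nucleoprotein filament with single-molecule FRET. Provides a
    Monte Carlo simulator of free 1D diffusion along a rigid filament rendered
    as camera-binned donor/acceptor intensity traces (two- and three-color),
    generators of discrete-state homology-recognition traces from a
    continuous-time Markov model, intensity corrections (background, leakage,
    gamma factor) and FRET efficiency computation, donor-acceptor
    cross-correlation analysis with single-exponential fitting, a simulation
    calibration table to infer the sliding diffusion coefficient from measured
    cross-correlation times, Gaussian-emission hidden Markov model idealization
    with transition density plots and transition-rate and recognition-efficiency
    statistics, and analytic estimates of sliding length and the facilitated
    target-search rate enhancement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    minpack.lm,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
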