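Package: spinquench
Title: Phase-Ordering Kinetics in the Two-Dimensional Long-Range Ising Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte Carlo simulation of domain coarsening in a two-dimensional
    ferromagnetic Ising model with power-law couplings J/r^n, using
    nonconserved single-spin-flip (Glauber) kinetics with Metropolis
    acceptance. Provides a compiled sweep engine, quench trajectory drivers,
    equal-time correlation functions and structure factors with spherical
    averaging, characteristic domain lengths, growth-law fits, dynamical
    scaling collapses against the Ohta-Jasnow-Kawasaki form, Porod tail
    diagnostics, temperature sweeps with susceptibility-peak critical-point
    estimation, and closed-form mean-field critical-temperature theory for
    the power-law potential.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
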