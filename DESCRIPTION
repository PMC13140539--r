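Package: emuflux
Title: Surrogate-Accelerated Isotopically Nonstationary Metabolic Flux Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for isotopically nonstationary metabolic flux analysis
    (INST-MFA) on compartmentalised, atom-mapped reaction networks. Simulates
    time-resolved mass isotopomer distributions (MIDs) by elementary metabolic
    unit (EMU) decomposition and stiff ODE integration, samples the steady-state
    flux polytope and pool-size space, trains small fully connected neural
    network surrogates that replace the ODE solver inside estimation, fits
    fluxes and pool sizes to measured MIDs by bounded weighted least squares
    minimising the reduced chi-square statistic, computes per-reaction profile
    confidence intervals, and quantifies flux recoverability by per-reaction
    Pearson correlation against sampled ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    deSolve,
    minpack.lm,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
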