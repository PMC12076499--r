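Package: crnode
Title: Hybrid Mechanistic and Neural ODE Modeling of Chemical Reaction Networks
Version: 0.1.0
Authors@R:
    person("crnode", "maintainers", email = "crnode@example.org", role = c("aut", "cre"))
Description: Tools for modeling chemical reaction network (CRN) kinetics with
    mass-action ordinary differential equations augmented by a trainable neural
    correction term (a universal differential equation). Provides declarative
    reaction-network definitions with batch and flow (CSTR) reactors, a stiff
    adaptive implicit Runge-Kutta solver with continuous-adjoint gradients, an
    LSTM-based correction network trained on noisy concentration time series,
    per-species neural-contribution extraction for diagnosing hidden reactions,
    synthetic measurement generation, and oscillation analysis (period
    estimation, sustained/damped classification, and phase-space scans over
    inflow concentrations).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    numDeriv,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
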