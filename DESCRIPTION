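Package: burstmodes
Title: Deterministic Fixed Points Versus Stochastic Modes in Bursty Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and exact analysis of autoregulated gene expression with
    geometrically distributed protein bursts. Computes, side by side, the
    deterministic mass-action description (fixed points, stability, ODE
    trajectories) and the chemical master equation description (exact recursive
    stationary distribution, transient dynamics on a truncated lattice, moments,
    modes, mean first-passage times) of a protein whose production rate is an
    arbitrary monotone feedback function of its own copy number. Includes an
    exact Gillespie direct-method simulator for general elementary reaction
    networks and for the burst model, system-size scaling experiments, regime
    classification (mono-/bistable crossed with uni-/bimodal), and matched-model
    constructions that isolate how burst size and feedback nonlinearity shape
    the sharpness of the stationary distribution.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    yaml,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
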