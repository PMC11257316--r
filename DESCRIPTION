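Package: ciket
Title: Michaelis-Menten Kinetics with Fully and Partial Competitive Inhibition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dimensionless rate-equation toolkit for Michaelis-Menten enzyme
    kinetics under fully and partial competitive inhibition. Provides ODE
    simulators (explicit Euler and an adaptive reference integrator) for both
    reaction schemes and their phi-approximation linear system, the family of
    quasi-steady-state velocity expressions (classical and refined sQSSA,
    total QSSA, cubic phase-space forms), Lambert-W pre-steady-state
    solutions, biexponential time courses, steady-state timescale and error
    analysis with validity conditions, multi-steady-state detection governed
    by the acceleration-factor ratio delta, pre/post-steady-state
    intersection solvers for steady reactant levels, and a synthetic
    velocity-data generator with nonlinear least-squares parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
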