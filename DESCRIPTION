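Package: biopepa
Title: Reagent-Centric Reaction Networks with Deterministic and
    Stochastic Semantics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A kernel for mass-action biochemical reaction networks written
    in the reagent-centric style of the Bio-PEPA process algebra: species are
    declared with their per-reaction roles (reactant, product, activator,
    inhibitor) and stoichiometry, and the reaction-centric stoichiometric
    form is derived from them.  Models can be built programmatically or
    parsed from a small text format.  Every model gets two exact semantics:
    an ordinary-differential-equation interpretation integrated with a
    stiff-capable adaptive solver, and a continuous-time Markov chain
    simulated with the Gillespie direct method, plus steady-state detection,
    volume scaling, replicate averaging, extinction (deadlock) analysis, and
    a uniformization-based transient oracle for verification.  Ships presets
    for Rosen's (M,R) metabolism-replacement system, whose closed catalytic
    cycle exhibits a live steady state, a degradation-driven collapse, and
    stochastic extinction under deterministically viable parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
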