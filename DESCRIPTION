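Package: stochmom
Title: Moment-Based Parameter Inference for Stochastic Reaction Networks
Version: 0.1.0
Authors@R:
    person("Maintainer", "stochmom", email = "stochmom@example.org",
           role = c("aut", "cre"))
Description: Generalized method of moments (GMM) estimation of mass-action
    rate constants in discrete-state stochastic reaction networks from
    population snapshot data (as produced by flow cytometry).  Theoretical
    moments are obtained by symbolic derivation and numerical integration of
    moment-closure ordinary differential equations (zero central-moment
    closure) or by the hybrid method of conditional moments, in which
    low-copy species define discrete modes and high-copy species are
    described by partial moments conditioned on each mode.  Includes an
    exact Gillespie stochastic simulation algorithm for generating snapshot
    datasets, the two-step, demean, demean-diagonal, iterated and
    continuously-updating GMM estimator variants, a multistart bounded
    optimizer, and a replication harness for parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
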