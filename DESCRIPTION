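Package: ratemoments
Title: Non-Equilibrium Moment-Closure Statistics for Stochastic Firing-Rate Networks
Version: 1.0.0
Authors@R:
    person("ratemoments", "developers", email = "ratemoments@example.org",
           role = c("aut", "cre"))
Description: Computes the complete time-varying first- and second-order
    statistics (means, variances, covariances of both activity and firing)
    of heterogeneous Wilson-Cowan type firing-rate networks driven by
    instantaneously correlated background noise. A bivariate-Gaussian
    moment closure turns the network of coupled stochastic differential
    equations into a small system of nonlinear ordinary differential
    equations; a quasi-steady-state baseline and an Euler-Maruyama
    Monte Carlo ensemble simulator with error bands provide reference
    solutions, and an evaluation layer measures average absolute error
    across coupling-strength sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
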