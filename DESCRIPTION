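Package: ikrfit
Title: Fitting Two-Gate Hodgkin-Huxley Models of the Rapid
    Delayed-Rectifier Potassium Current to Voltage-Clamp Data
Version: 0.1.0
Authors@R: person("ikrfit", "developers", role = c("aut", "cre"),
    email = "ikrfit@example.org")
Description: Tools for characterising hERG/IKr channel kinetics from
    whole-cell voltage-clamp recordings with a two-gate Hodgkin-Huxley
    model. Implements four complementary fitting strategies: direct
    algebraic fits to steady-state and time-constant summary curves,
    optimisation against simulated summary curves, whole-trace fitting to
    conventional step protocols, and whole-trace fitting to a short
    sinusoidal protocol. Includes exact piecewise-analytic and adaptive
    ODE simulation of voltage protocols, summary-curve extraction with
    capacitance-artifact blanking, bounded log-transformed CMA-ES
    optimisation with multi-start reliability analysis, a synthetic-cell
    generator with known ground truth, and a cross-validation workbench.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
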