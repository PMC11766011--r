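Package: vsdgate
Title: Voltage-Sensor S4 Deactivation Modelling and Nav Whole-Cell Gating Analysis
Version: 0.1.0
Authors@R:
    person("VSD", "Gate Maintainers", email = "maintainers@vsdgate.example.org",
           role = c("aut", "cre"))
Description: Tools for studying voltage-sensing domain (VSD) gating of sodium
    channels along two arms. The structural arm builds toy four-helix voltage
    sensors, steers the S4 "sliding helix" through a stepped deactivation
    (downshift) trajectory under plane constraints and flat-bottom positional
    restraints with Monte-Carlo energy minimization over a documented surrogate
    energy, and analyses salt bridges, charged-pair distances and S4 rotation
    along trajectories. The electrophysiology arm simulates whole-cell sodium
    currents under IV, steady-state inactivation, fast inactivation and
    two-pulse recovery protocols from a known gating truth, and implements the
    complete analysis chain: sweep features (peak, time to peak, 50% decay),
    current density, chord-conductance transform, Boltzmann activation and
    availability fits, bi-exponential recovery fits and two-group statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
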