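Package: apcontrib
Title: Contribution Analysis of Ion-Channel Gating Kinetics to the Cardiac Action Potential
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies how much each Hodgkin-Huxley gating variable speeds up
    or slows down each region of an action potential.  A gate's time constant
    is perturbed multiplicatively over inflection-bounded intervals (epochs) of
    a simulated trajectory and the fractional change in the interval duration,
    normalised by the perturbation fraction, is its contribution.  Ships a
    generic declarative Hodgkin-Huxley model core, stiff (BDF/Gear) simulation
    under current-clamp stimulus protocols, automatic segmentation of the
    action potential into phases, epochs and intervals of interest with APD
    metrics, a bundled 30-state adult rat left-ventricular myocyte model with
    sarcoplasmic-reticulum calcium handling, and analytic fixtures with exact
    closed-form contributions for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    yaml,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
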