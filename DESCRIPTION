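Package: memcap
Title: Memcapacitance Modelling and Paired-Ramp Estimation for Bilayer Lipid Membranes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models a solvent-containing bilayer lipid membrane under periodic
    triangular voltage clamp as a nonlinear viscoelastic memcapacitor. Provides
    closed-form first-order perturbation solutions for the current response,
    pinched capacitance-voltage hysteresis loops, apparent (possibly negative)
    conductance and the work done by the voltage source per period; an exact
    numerical ODE reference for the same equivalent circuit; a first-order
    model of the voltage-clamp amplifier feedback filter; a synthetic
    voltage-clamp trace generator; and the paired-ramp analysis pipeline that
    folds recorded currents over the drive cycle and recovers all
    equivalent-circuit parameters by half-sum/half-difference decomposition,
    transient fitting and exact-model refinement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
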