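Package: neqfe
Title: Non-Equilibrium Free Energy Estimation for Alchemical Binding
    Calculations
Version: 0.1.0
Authors@R:
    person("neqfe", "developers", email = "neqfe@example.org",
           role = c("aut", "cre"))
Description: Estimation of free energy differences from non-equilibrium
    alchemical work measurements. Reads dH/dlambda traces produced by
    molecular dynamics engines, integrates them into work values, and
    provides uni-directional (Jarzynski) and bi-directional
    (Bennett/Crooks maximum-likelihood, BAR) estimators with bootstrap
    uncertainties, a work-distribution overlap convergence diagnostic,
    the analytical Boresch restraint standard-state correction,
    thermodynamic-cycle assembly for absolute binding free energies,
    benchmark accuracy statistics with combined parametric and
    non-parametric bootstrap errors, and a Langevin toy simulator with
    analytically known free energy differences for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
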