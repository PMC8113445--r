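Package: lvtraits
Title: Trait-Based Inverse Calibration of Lotka-Volterra Community Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibrates a temperature-dependent Lotka-Volterra community
    model for species-rich plant communities from static abundance data and
    functional traits. A low-dimensional "transfer function" maps orthogonal
    trait axes to per-species demographic parameters through a hyperspherical
    parameterization of regression coefficients; its roughly eleven parameters
    are estimated by differential-evolution MCMC (DEzs, with past-state
    archive and snooker updates) under a multinomial likelihood over
    equilibrium relative abundances. Includes equilibrium solvers (analytic
    fixed point and ODE integration), trait preprocessing (species averaging,
    log-transformation, correlation PCA), convergence diagnostics,
    model validation (Nagelkerke pseudo-R2, DIC, trait-randomization null
    models, presence/absence AUC), posterior trait-demography summaries, a
    synthetic-community generator, and a parameter-recovery harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    pROC,
    stats,
    utils,
    yaml
Suggests:
    coda,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
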