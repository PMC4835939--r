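Package: sscfkin
Title: Kinetic Simulation, Feed Design and Parameter Estimation for
    High-Solids SSCF of Pre-Treated Lignocellulose
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates enzymatic hydrolysis and simultaneous
    saccharification and co-fermentation (SSCF) of pre-treated
    lignocellulose with a compact kinetic model: second-order cellulase
    adsorption, glucose- and ethanol-inhibited cellulose hydrolysis,
    proportional xylan release, Monod glucose uptake, constant-yield
    ethanol production and ethanol-induced cell death. Provides a
    model-based fed-batch design loop that schedules solid feeds from a
    cellulose-conversion trigger under an instantaneous solids (WIS)
    ceiling, joint estimation of the four hydrolysis parameters from
    batch time courses with residual-bootstrap confidence intervals, and
    a synthetic time-course generator for testing and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
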