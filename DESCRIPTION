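Package: ehsim
Title: Two-Phase Substrate Kinetics for Enzymatic Hydrolysis of Lignocellulose
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Phenomenological reaction model for the enzymatic saccharification
    of pretreated lignocellulose in which cellulose is split into a facile and a
    recalcitrant population. Implements closed-form equilibrium partitioning of
    a lumped enzyme cocktail among substrates and soluble inhibitors,
    first-order hydrolysis and lignin-solubilization kinetics, batch and
    continuous membrane-reactor (CSTR with ultrafiltration liquor removal)
    simulation, constrained Nelder-Mead parameter calibration against measured
    glucose, xylose and insoluble-solids time series, one-at-a-time local
    sensitivity sweeps, and a synthetic-data generator emulating the supported
    experimental designs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    readr,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
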