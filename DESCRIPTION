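Package: floralhydra
Title: Runaway Xylem Cavitation in Flowering Stems Under Combined Heat and
    Water Stress
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse and simulate hydraulic failure of flowers during
    combined heat and drought stress. Provides evaporative-flux physics (Buck
    vapour pressure deficit, residual conductance/transpiration conversion,
    temperature corrections of hydraulic conductance and surface tension),
    sigmoid xylem vulnerability curves with fitting and inversion, the
    analytical runaway-cavitation threshold (the percentage loss of
    conductance at which residual evaporative demand exceeds maximum possible
    xylem supply), a compact SurEau-style soil-plant-atmosphere hydraulic
    simulator with per-organ symplast/apoplast compartments and cavitation
    dynamics, an optical-vulnerability image-differencing pipeline for
    detecting cavitation events in time-lapse stacks together with a
    stem-shrinkage water-potential proxy, and seeded synthetic-data generators
    with known ground truth for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
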