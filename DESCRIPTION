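Package: pilespot
Title: Hot- and Cold-Spot Monitoring for Aerated Static-Pile Biostabilization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for spatio-temporal monitoring of aerobic biostabilization
    of the organic fraction of municipal solid waste in aerated static-pile
    bioreactors. Models the probe sampling grid of a weekly measurement
    campaign (temperature, O2, CO2, CO at fixed cross-sections), reconstructs
    continuous fields on masked regular grids using natural-neighbor (Sibson)
    interpolation for cross-sections and radial-basis-function interpolation
    for longitudinal sections with atmospheric and aeration-channel boundary
    conditions, classifies localized hot spots (overheated, oxygen-depleted)
    and cold spots (under-sanitized) from simultaneous threshold criteria,
    and aggregates campaign-level spot inventories. A synthetic campaign
    generator with two-phase thermal dynamics, O2/CO2 inverse coupling,
    temperature-driven CO and injectable anomalies provides ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    mgcv,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    jsonlite,
    optparse
Config/testthat/edition: 3
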