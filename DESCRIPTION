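Package: strainpump
Title: Modelling and Analysis of Skin-Strain-Actuated Microfluidic Pumps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analytical and dynamic models of valveless microfluidic pumps
    actuated by skin strain. Implements strain-dependent hydraulic resistances
    of rectangular microchannels with asymmetric aspect ratios, an
    equivalent-circuit flow-divider model of per-cycle pumping efficiency with
    aspect-ratio sweeps, a transient lumped-network simulation of repeated
    strain cycles with meniscus tracking, projection of principal Lagrangian
    strain fields onto a sensor orientation, and the downstream statistics used
    to reduce meniscus-displacement measurements (pumping-efficiency slopes,
    pumping rates, correlations, box summaries). Includes seeded synthetic
    generators for every input so the full pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    deSolve,
    mgcv,
    stats,
    utils,
    yaml,
    jsonlite,
    optparse,
    readr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
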