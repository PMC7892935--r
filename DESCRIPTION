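Package: injeradry
Title: Coupled Heat and Mass Transfer Simulation of Injera Convective Drying
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates convective tunnel drying of injera, a porous
    high-moisture flatbread, by solving the coupled moisture and energy
    equations through the sample thickness with a non-equilibrium
    evaporation source term and convective boundary transfer. Ships
    composition- and temperature-dependent thermophysical property models
    (Choi-Okos component correlations), a water-activity sorption isotherm,
    convective heat and mass transfer coefficient correlations, thin-layer
    drying-kinetics fitting (Henderson-Pabis, Page, two-term) with
    goodness-of-fit statistics and model ranking, slope-method effective
    moisture diffusivity extraction, a balanced two-factor ANOVA for
    factorial drying experiments, and a seeded synthetic tunnel-dryer data
    generator for validation studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
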