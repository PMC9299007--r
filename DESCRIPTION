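Package: socpotential
Title: Global Cropland Soil Organic Carbon Sequestration Potential from
    Meta-Analytical Effect Sizes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the global potential of improved cropland management
    to sequester soil organic carbon (SOC). Harmonizes meta-analytical SOC
    effect sizes (stock and concentration changes) into annual stock changes
    with standard errors, pools them per management intervention and climate
    zone by fixed-effect inverse-variance weighting, stratifies cropland area
    by current management (fertilization, manure input, tillage, rotation,
    residue fate), constrains the organic-fertilization measure by a
    recyclable-manure carbon budget, and upscales to per-measure potentials
    with Monte-Carlo uncertainty bounds and complementarity scenarios. A
    seeded synthetic-data generator reproduces the statistical structure of
    the global cropland input layers so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
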