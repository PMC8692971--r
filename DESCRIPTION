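Package: octopop
Title: Quantitative Monitoring of Habitat-Forming Octocoral Populations
Version: 0.1.0
Authors@R:
    person("Octopop", "Maintainers", email = "maintainers@octopop.invalid",
           role = c("aut", "cre"))
Description: Tools for long-term quantitative monitoring of habitat-forming
    octocoral populations (Paramuricea clavata, Corallium rubrum) on
    Mediterranean coralligenous reefs. Reads and validates colony-level
    quadrat survey tables, computes the standard demographic indicators
    (percentage of affected colonies, mean injury extent, density, allometric
    live biomass, size structure), reconstructs pre-disturbance baselines
    from the recent/old injury classification, fits species-specific
    self-thinning lines and maps log-log biomass-density trajectories
    against them, detects marine heatwaves from daily temperature series
    against a fixed-baseline day-of-year climatology, and counts in-situ
    extreme-heat days with absolute temperature floors. A synthetic-data
    generator produces survey and temperature fixtures with known ground
    truth, and a command-line entry point orchestrates the pipeline.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
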