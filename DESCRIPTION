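Package: streamimpact
Title: Bioassessment of Metal-Contamination Impacts on Stream Macroinvertebrates and Fishes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for assessing ecological impacts of trace-metal contamination
    in rivers from paired contaminated/reference field surveys. Computes
    cumulative criterion units (CCU) against hardness-adjusted U.S. EPA chronic
    water-quality criteria with explicit handling of below-LOQ concentrations,
    benthic macroinvertebrate community metrics and dominant-family abundances
    from stone-level samples, fish abundance and Fulton-type condition factor,
    and a two-gate effect classification combining 90% prediction-interval
    reference ranges with single-step (max-|t|) multiplicity-adjusted paired
    site contrasts. Includes a synthetic-data generator that emulates the
    nine-site study design so the operating characteristics of the whole
    procedure can be evaluated by simulation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    mvtnorm
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    withr,
    jsonlite
Config/testthat/edition: 3
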