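Package: hazardCoex
Title: Census-Tract Coexposure to Extreme Heat, Wildfire Burn Zones, and
    Wildfire Smoke
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Classifies census tract-days as exposed to extreme heat
    (dual relative/absolute temperature thresholds), wildfire burn zones
    (active-fire point presence), and wildfire smoke (modeled smoke PM2.5
    above a threshold), builds same-day and two-day coexposure flags for
    every hazard combination, and summarises exposure with tract-day and
    person-day metrics, Mann-Kendall trend tests on annual series, and
    sociodemographic disparity analyses (exposure-quintile composition by
    race/ethnicity, social-vulnerability overlays, tribal-land comparisons,
    top-ranked tract tables). A synthetic-data generator produces tract
    lattices, seasonal temperature fields with planted heat events,
    summer-weighted fire ignitions, and decaying smoke plumes, so the whole
    pipeline runs and is testable offline. Hazard matrices are held in a
    SummarizedExperiment-derived container with tracts as rows and days as
    columns.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'HazardExperiment.R'
    'classify.R'
    'coexposure.R'
    'metrics.R'
    'disparity.R'
    'io.R'
    'trend.R'
    'zonal.R'
    'simulate.R'
    'pipeline.R'
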