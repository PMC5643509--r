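Package: unicub
Title: Detection and Analysis of Uniparental Incubation in Biparental Shorebirds
Version: 0.1.0
Authors@R: person("Analysis", "Pipeline", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A pipeline for analysing continuous nest-monitoring data
    (nest/surface temperature loggers and RFID parent detections) from
    biparentally incubating shorebirds. Converts raw 5-second sensor
    streams into per-reading incubation state and parent-labelled
    incubation bouts, detects qualified uniparental incubation phases
    using a twice-the-population-median-bout rule, computes hourly and
    daily nest attendance with a 75 percent type-purity filter, and fits
    linear and binomial mixed-effects models of attendance and hatching
    success with simulation-based posterior summaries and variance
    components. Includes a synthetic-data generator with a ground-truth
    ledger for validating every stage, species/population summary
    tables, actogram rendering, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    lme4,
    MASS,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
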