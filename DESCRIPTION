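Package: stepagree
Title: Agreement Analysis and Simulation for Free-Living Wearable Step Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for validating consumer activity trackers against a
    research-grade reference accelerometer under free-living conditions.
    Implements the method-comparison workflow used in telemonitoring
    validation studies: ingestion of per-device epoch-level step streams,
    reference-defined nonwear detection and masking, aggregation to paired
    per-participant totals, Bland-Altman bias and 95% limits of agreement,
    the median absolute percentage difference (MAD) accuracy statistic, and
    leave-one-out cross-validated bias correction. A companion simulator
    generates ground-truth activity (a bout process with Normal cadence) and
    device-observed streams with configurable update intervals, systematic
    under- or over-counting, epoch noise, overnight step carryover, device
    malfunction and battery death, so the whole pipeline is testable without
    access to raw study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    readr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    withr
Config/testthat/edition: 3
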