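Package: roadvib
Title: Displacement-Index Vibration Analysis for Liquid-Semen Transport Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying road-induced vibration exposure during
    transport of liquid-preserved boar semen (and similar vibration-sensitive
    cold-chain goods) from tri-axial accelerometer logs. Implements the
    Displacement Index, a per-second vibration-intensity statistic built from
    Euclidean distances between consecutive acceleration readings; reads and
    writes a key-value data-logger text format with GNSS fixes and road
    annotations; summarizes standardized road trials with two-way ANOVA and
    Tukey HSD comparisons across road-surface and speed categories; analyzes
    field deliveries via intensity binning, road-quality classes, and
    detection of high-vibration road segments; and simulates seeded synthetic
    road traces calibrated to target vibration levels so every pipeline stage
    is testable without real transport recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
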