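Package: spotflux
Title: Processing and Reporting of Spot-Sampled Enteric Gas Emission Records
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for turning spot-sampled gas-flux visit records and
    feed-drop event logs from automated head-chamber systems (such as
    GreenFeed units) into per-animal emission phenotypes. Implements
    record-sufficiency filtering (minimum visit duration, minimum records
    per day, minimum days per week), single-pass per-gas outlier masking
    at mean +/- k*SD, duration-weighted daily and minute-weighted weekly
    aggregation, parameter-grid sensitivity sweeps, descriptive visitation
    and diurnal reports, pellet-intake accounting, and a seeded trial
    simulator so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    lubridate,
    rlang,
    stats,
    utils,
    jsonlite,
    yaml,
    withr,
    ggplot2,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
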