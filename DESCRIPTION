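Package: durlink
Title: Crossover Drug-Drug Interaction Alerts Under Patient Identity Linkage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for studying how patient identity
    resolution affects prospective drug utilization review (DUR). Generates
    synthetic pharmacy claim streams with realistic insurance churn
    (January-concentrated payor transitions, age-driven benefit changes,
    off-benefit cash fills), links claims to patients under a
    beneficiary-identifier regime and a deterministic demographic-matching
    unique-patient-identifier (UPI) regime, screens claims for serious
    drug-drug interaction alerts against the linked medication history, flags
    crossover alerts (alerts whose precipitating fill occurred under a
    different insurance identifier), classifies alert dispositions
    (override, replacement, abandonment), and projects undetected alert
    volumes to a national population via a market-share proportionality
    factor.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr (>= 1.1.0),
    tidyr,
    tibble,
    readr,
    purrr,
    rlang,
    jsonlite,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
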