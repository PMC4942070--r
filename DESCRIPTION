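Package: abdesign
Title: Exact Operating Characteristics for A+B Phase I Dose-Escalation Designs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Exact evaluation of rule-based A+B phase I dose-escalation
    designs (including the classical 3+3), with and without dose
    de-escalation. Every possible trial pathway is enumerated together with
    its exact occurrence probability, from which scenario operating
    characteristics are computed: the sample-size distribution,
    experimentation and maximum-tolerated-dose (MTD) recommendation
    percentages per dose level, the expected toxicity level (ETL), the
    expected overall toxicity rate (EOTR), the mean number of dose-limiting
    toxicities (DLTs) and the distribution of within-trial DLT rates.
    Scenario-independent design characteristics are also provided: the
    terminal data states possible at the selected MTD with exact
    Clopper-Pearson and Wilson score confidence intervals, the escalation
    probability curve and its tipping point. A seeded Monte-Carlo trial
    simulator serves as an independent cross-check of the exact engine, and
    a command-line report generator exports tables, plots and a Markdown
    summary for a chosen design and dose-toxicity scenario.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    commonmark,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
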