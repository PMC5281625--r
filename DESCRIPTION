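Package: micdiag
Title: Metabolomic and Metagenomic Diagnostics for Microbially Influenced
    Pipeline Corrosion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for diagnosing microbially influenced corrosion (MIC) in
    oil-production pipelines from combined untargeted metabolomics and
    metagenomics. Implements exact-mass metabolite annotation with
    retention-time prediction by a six-descriptor linear model, targeted
    screening for fumarate-addition metabolites (alkyl- and
    benzylsuccinates), the nitrogen-rule odd-nominal-mass abundance
    statistic, differential-feature comparison between high- and
    low-corrosion systems, per-million gene-frequency normalization, and
    coverage-based estimation of the community fraction carrying
    terminal-electron-acceptor pathways. A seeded synthetic-data generator
    emulates triplicate two-mode LC-MS feature tables with ion-counting
    shot noise and genome-bin communities with configurable pathway
    content, so every stage is testable without raw instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
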