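Package: treatcycles
Title: Treatment-Cycle Graphs from Hospital Stay Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers directed, labelled "treatment cycle" graphs from hospital
    stay records (one row per stay on a nursing organizational unit), classifies
    their structure (empty, linear, cyclic), computes topological indices
    including the Wiener index and a directed version of the Randic connectivity
    index, and tabulates unit and transfer frequencies across a cohort. Includes
    a calibrated synthetic-cohort generator so every stage of the pipeline can be
    exercised and tested without access to clinical data, plus a reproducible
    report pipeline writing summary tables, per-graph exports and frequency
    rankings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
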