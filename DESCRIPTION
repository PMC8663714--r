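Package: recruitlag
Title: Distributed-Lag Modelling and Cost-Effectiveness Metrics for
    Cohort Recruitment Campaigns
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate participant recruitment campaigns for
    population cohort studies: finite distributed-lag regression of daily
    recruit counts on campaign events, information-criterion lag-length
    selection, completion-rate, completion-delay and cost-per-completer
    accounting with staff-time schedules, demographic composition by
    recruitment method, and a synthetic-data generator emulating a
    three-city Canadian recruitment effort so the full pipeline is
    testable without participant-level data.
License: MIT + file LICENSE
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
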