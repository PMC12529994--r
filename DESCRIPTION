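Package: htngap
Title: Country-Level Hypertension Care Demand and Health-Workforce Capacity Gaps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the gap between the clinic visits a country's population
    with hypertension needs and the visits its health workforce can deliver.
    Demand is prevalence times eligible population times an assumed visit
    schedule (12, 6, 3, or 1 visits per patient per year); supply is provider
    density times population times clinic throughput (20 or 10 patients per
    day over 200 workdays) times the share of provider time spent on
    hypertension care, under physician-only, nonphysician-only, and
    team-based care models. Includes readers for World Bank indicator and
    NCD-RisC-style prevalence tables, a synthetic country-level data
    generator with income-group-conditional distributions, per-country and
    income-group gap summaries with uncertainty intervals propagated from
    prevalence confidence limits, and a reproducible pipeline with a
    command-line wrapper.
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
    jsonlite,
    purrr,
    readr,
    rlang (>= 1.0.0),
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
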