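Package: eceasim
Title: Extended Cost-Effectiveness Microsimulation of Cash Transfers for
    Diabetes Care
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An individual-level annual-cycle Markov microsimulation of the
    diabetes care cascade in South Africa, used to evaluate conditional cash
    transfer (CCT) strategies that subsidise attendance at diagnosis and
    treatment services. The model tracks costs from a health-system
    perspective, out-of-pocket spending, disability-adjusted life years and
    catastrophic health expenditure, and reports extended cost-effectiveness
    outcomes (incremental net monetary benefit, financial risk protection)
    disaggregated by income quintile and sex, with probabilistic, one-way and
    population-replicate sensitivity analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
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
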