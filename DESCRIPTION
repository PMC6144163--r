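Package: cessim
Title: Cost-Effectiveness Modelling of Smoking Cessation Programs for
    Cancer Patients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A Markov cohort state-transition model for evaluating the
    cost-effectiveness of smoking cessation programs offered to newly
    diagnosed cancer patients. Implements smoking-status-adjusted
    background mortality derived from life tables and cause-of-death
    splits via hazard ratios, duration-dependent relapse through tunnel
    states, discounted cost/QALY/life-year accrual, incremental
    cost-effectiveness analysis, one-way (tornado) deterministic
    sensitivity analysis, and probabilistic sensitivity analysis with
    cost-effectiveness plane and acceptability curves. Ships a complete
    default parameter set and a synthetic life-table generator so the
    whole pipeline runs with zero external inputs.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
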