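Package: earlyhta
Title: Early Health Economic Evaluation of Clinical Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Staged early health-technology assessment for data-driven
    clinical analytics: a data-feasibility auditor for candidate development
    datasets (sample size, follow-up, missingness), a PICO-structured
    barrier ledger with go/no-go verdicts, and a cohort-level economic
    evaluation engine combining decision-tree rollback with discrete-time
    Markov state-transition models. Outcomes include discounted costs,
    life-years, QALYs, ICERs, net monetary benefit and headroom, with a
    full uncertainty toolkit (one-way/tornado analysis, scenario analysis,
    probabilistic sensitivity analysis, cost-effectiveness acceptability
    curves, threshold search and parameter sweeps). Ships two worked case
    models: risk stratification of watch-and-wait chronic lymphocytic
    leukaemia, and early detection of catheter-related bloodstream
    infection in intensive care.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ggplot2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
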