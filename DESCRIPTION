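Package: peanutCEA
Title: Cost-Effectiveness Microsimulation of Commercial Peanut Immunotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Markov cohort model and individual-level microsimulation comparing
    epicutaneous peanut immunotherapy (EPIT), oral peanut immunotherapy (POIT),
    and no-immunotherapy strict avoidance in children with peanut allergy.
    Computes lifetime discounted costs and quality-adjusted life-years, event
    trackers for anaphylaxis and food-allergy fatality, incremental
    cost-effectiveness ratios and net monetary benefit, value-based ceiling
    prices by bisection, and a sensitivity-analysis suite (tornado diagrams,
    utility-cost surfaces, risk-reduction grids, probabilistic sensitivity
    analysis, and named scenario presets). Ships the published input set, a
    Gompertz-Makeham synthetic life table with a CSV loader for real tables,
    and deterministic, seed-reproducible engines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
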