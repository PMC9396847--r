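Package: ceatree
Title: Decision-Tree Cost-Effectiveness Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A decision-analytic engine for cost-effectiveness analysis on
    decision trees: exact expected-value evaluation by rollback with a
    path-enumeration oracle, incremental cost-effectiveness metrics (ICER,
    net monetary benefit, dominance, efficiency frontier), deterministic
    one-way sensitivity analysis with threshold finding and tornado
    ranking, and seeded probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves. Ships a worked health-economic
    case study comparing antibiotic prophylaxis against no antibiotics at
    dental implant placement from patient and healthcare perspectives,
    plus a generator of random valid trees for property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
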