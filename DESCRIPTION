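Package: gcea
Title: Generalized Cost-Effectiveness Analysis of Cancer Control Programmes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for WHO-CHOICE-style generalized
    cost-effectiveness analysis (GCEA) of breast, cervical and colorectal
    cancer interventions. Provides validated natural-history state graphs,
    a deterministic annual-cycle Markov cohort engine for open populations
    (including a dynamic two-sex HPV transmission sub-model), a catalog of
    fourteen prevention, screening, treatment and palliative-care
    interventions evaluated against a hypothetical null scenario,
    disability-weighted healthy-life-year accounting with discounting,
    ingredients-based intervention costing, and a constrained
    expansion-path optimizer producing league tables and budget
    allocations. A seeded synthetic-data module generates internally
    consistent region parameter bundles so the whole pipeline runs with no
    external data.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
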