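Package: fertimass
Title: Transpiration-Driven Nutrient Mass Balance for Fertigation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for transpiration-driven nutrient mass-balance analysis in
    containerized crop production. Estimates per-element nutrient uptake from
    pour-through solution depletion, derives whole-plant water-use efficiency
    from gravimetric container mass logs, predicts required fertigation input
    concentrations from organ tissue chemistry (organ-explicit and organ
    biomass-weighted), scores prediction deviations against measured uptake,
    and runs the associated statistical comparisons (repeated-measures ANOVA
    with marginal-means contrasts, Welch tests, influence diagnostics). A
    mass-conserving synthetic fertigation-trial generator with a ground-truth
    ledger makes the whole pipeline testable end to end.
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
    emmeans,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
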