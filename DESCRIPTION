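Package: onrisk
Title: Uncertainty-Aware Optimum Nitrogen Rates, Yield-Loss Risk, and
    Environmental Benefits for Maize
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Fits hierarchical Bayesian quadratic-plateau models to maize
    nitrogen-rate trials laid out as randomized complete block designs, and
    propagates the full posterior into decision-relevant quantities: the
    agronomic and economic optimum nitrogen rates (AONR, EONR) as posterior
    distributions, the probability and expected size of yield loss under
    staged nitrogen-rate reductions, and the resulting changes in nitrous
    oxide emissions, nitrate leaching, fertilizer-manufacture carbon dioxide,
    and their monetized social benefit scaled to regional planted area.
    Includes a randomized-complete-block trial simulator so the whole
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    rjags,
    coda,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
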