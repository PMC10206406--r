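Package: vegchain
Title: Discrete Event Simulation of Perishable Vegetable Supply Chains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discrete event simulator for perishable vegetable supply chains
    in low-resource settings. Models a three-level market network (village
    markets, a tiered bidirectional wholesale trade network, and retailers)
    with age-tracked produce lots, expiration and Poisson breakage losses,
    seasonal supply with a state-level import/export equilibrium, order-up-to
    replenishment policies, perishability-prioritised vehicle loading, and
    first-expire-first-out dispatch. Computes demand fulfillment, postharvest
    loss disaggregated by mechanism and supply chain stage, and time through
    the chain, and runs production-multiplier scenario experiments on
    synthetic networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
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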