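Package: mopane
Title: Ecosystem Service Trade-Offs of Charcoal Production in Mopane Woodlands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An ecological production-function pipeline for quantifying
    trade-offs between charcoal production and other provisioning ecosystem
    services (firewood, construction wood, wild food, medicinal plants,
    grass) in southern African Mopane woodlands. Computes plot-level
    woodland structure from stem inventories (taper-corrected DBH,
    allometric above-ground biomass, diversity, grass quadrats,
    line-intersect coarse woody debris), derives a woodland typology by
    Bray-Curtis clustering with Calinski-Harabasz selection of the number
    of types, links services to species via a use table, upscales per-type
    availability to village landscapes with propagated standard errors,
    and evaluates counterfactual charcoal-harvest scenarios with 95%
    confidence intervals. Includes a seeded synthetic-data generator that
    emulates a village chronosequence field study so the whole pipeline is
    testable end to end.
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
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vegan
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
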