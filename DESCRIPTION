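Package: miomboAGC
Title: Aboveground Carbon, Tree Diversity and Sampling Design for Dry
    Woodland Inventory Plots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing stem-level forest inventories from
    seasonally dry tropical woodlands such as miombo. Converts diameter
    measurements to aboveground carbon (AGC) with a configurable power-law
    allometry, summarises stand structure (5-cm size classes, biomass
    hyperdominance, minimum-diameter sensitivity), computes tree
    alpha-diversity (richness, Fisher's alpha, individual-based
    rarefaction) and beta-diversity (Bray-Curtis, NMDS, PerMANOVA), fits
    and selects among candidate biomass-diversity functional forms by
    AICc, and simulates randomly placed subplots to quantify how plot
    size affects richness and AGC estimates. A spatially explicit
    synthetic stand generator with known ground truth (log-series species
    abundances, Poisson or Thomas-cluster stem placement, nested
    large-tree census windows) makes the whole pipeline testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
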