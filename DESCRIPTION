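Package: farmstyles
Title: Agent-Based Simulation of Smallholder Farming Styles, Climate and
    Food Security
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An annual-timestep agent-based model of a hypothetical rural
    community of 250 producer-consumer smallholder households on a 21x21 grid
    of 1-ha plots. Subsistence ('orphan') households may develop by adopting a
    labour-intensive peasant style (agroecology) or a capital- and
    market-dependent entrepreneurial style, under user-chosen climate change,
    agricultural policy, style-preference and global price transmission
    scenarios. The package provides the full simulation engine, a seeded
    Monte-Carlo batch runner for scenario grids and sensitivity analyses, and
    tracked outcomes including total production, local food price, farm
    conversions and abandonments, orphan nutrition, farm labour, income
    inequality (Gini), net farm incomes and real land productivity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
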