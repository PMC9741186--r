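Package: luccarbon
Title: Land-Use-Change Carbon Stock Accounting and CA-Markov Projection
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ecosystem carbon accounting driven by land-use and
    land-cover change (LUCC) on categorical rasters. Cross-tabulates land-use
    maps from two epochs into transfer matrices with net flows and conversion
    fractions, performs four-pool (aboveground, belowground, soil, dead
    organic matter) carbon-density bookkeeping of per-class and total stocks,
    projects class areas forward with row-stochastic Markov transition
    matrices, spatially allocates projected totals with a cellular-automata
    neighborhood-suitability rule, and validates simulated maps with Cohen's
    kappa. Includes a synthetic landscape generator with known transition
    dynamics, fixtures for a six-class provincial case study, and a
    configurable end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
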