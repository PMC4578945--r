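Package: betashift
Title: Spatio-Temporal Beta-Diversity Decomposition for Community Monitoring Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse community monitoring data (observations by species
    abundance or biomass tables) through both space and time. Decomposes the
    quantitative percentage-difference (Bray-Curtis) dissimilarity into
    replacement and abundance-difference components, computes total beta
    diversity and Local Contributions to Beta Diversity (LCBD) with permutation
    tests, summarises components within spatial and temporal strata (triangle
    plots), fits linear, quadratic and logistic temporal trajectory models,
    tests space-time structure by permutation redundancy analysis, locates
    compositional shifts with multivariate regression trees and chronological
    clustering, and attributes shifts to species via indicator values and RDA
    scores. Includes a synthetic generator of disturbance-driven multi-site
    community time series for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse,
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
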