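Package: aquachem
Title: Groundwater Hydrochemistry, Water Quality and Nitrate Health Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidy tools for island and coastal groundwater survey data:
    milliequivalent conversions and charge-balance quality control, descriptive
    statistics and hydrochemical facies diagnostics (Piper coordinates,
    Shchukarev water types, Gibbs ratios, endmember and chloro-alkaline
    indices), a weighted water quality index (WQI) with effective-weight
    attribution, irrigation suitability via sodium adsorption ratio, soluble
    sodium percentage and residual sodium carbonate with Wilcox and USSL
    classification, and non-carcinogenic nitrate hazard quotients for four age
    groups with deterministic and Monte Carlo exposure modelling. Includes a
    seeded Gaussian-copula generator of realistic survey datasets for testing
    and method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    generics,
    stats,
    utils,
    ggplot2,
    readr,
    Matrix,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
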