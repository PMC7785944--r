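Package: florsel
Title: Phenotypic Selection and Path Analysis of Floral Colour Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the statistical pipeline of a phenotypic-selection
    study on flower colour in the shore campion (Silene littorea):
    image-based R:G anthocyanin colour indices with two-point gray-standard
    calibration, female and male fitness components derived from raw flower,
    fruit, seed and pollen-assay counts, Lande-Arnold selection opportunities,
    standardized selection differentials and gradients, and a linear
    recursive path-analysis (structural equation) engine with maximum
    likelihood fitting, near-saturated model enumeration with
    covariance-equivalence deduplication, AIC/BIC model selection, nested
    chi-square comparisons, backward trimming, nonparametric bootstrap
    standard errors and indirect effects. A calibrated synthetic-data
    generator emulates the study's two populations so every stage is
    testable without the unreleased field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    car,
    png,
    tiff
Config/testthat/edition: 3
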