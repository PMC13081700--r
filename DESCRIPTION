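Package: netdom
Title: Network Enrichment Testing with Ordinal Dominance Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Permutation-based network enrichment testing for brain-wide
    association studies. Implements an intersection-union test built on
    ordinal dominance curves with a data-adaptive lower-quantile truncation
    parameter, mass-univariate linear model fitting with Freedman-Lane,
    simple, and stratified phenotype permutation, and four comparator
    enrichment tests (Fisher's-exact thresholding, mean-difference tests
    against spin-rotation and variogram-matched surrogate maps, and a
    weighted Kolmogorov-Smirnov permutation test). Includes a synthetic-data
    generator for spatially autocorrelated imaging fields and a rejection-rate
    study harness for type-I-error and power experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
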