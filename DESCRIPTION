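Package: arealscan
Title: Spatial and Space-Time Scan Statistics for Areal Disease Data
Version: 0.1.0
Authors@R:
    person("Avery", "Quinn", email = "avery.quinn@example.org",
           role = c("aut", "cre"))
Description: Cluster detection for areal (county-level) disease registry
    data: covariate-adjusted Poisson spatial scan statistics with circular
    and flexibly shaped windows, space-time Poisson and space-time
    permutation scans, conditional Monte Carlo and Gumbel significance,
    indirect standardization of stratified incidence, a synthetic registry
    generator for validation, and Table-style reporting with GeoJSON
    export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
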