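Package: coreconn
Title: Habitat Cores, Corridor Networks and Conservation Prioritization
    for Fragmented Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible workflow for national-scale conservation
    assessments of elusive species: reliability-based quality control and
    spatial thinning of occurrence records, percentile thresholding of a
    habitat-suitability surface, extraction of minimum-area habitat cores
    from natural land cover, circuit-theory corridor networks over a
    human-footprint resistance surface (cost-weighted distances,
    least-cost paths, current-flow centrality), multi-criterion core
    prioritization, density-based population extrapolation, and
    protected-area gap and temporal-coverage analysis. Includes a seeded
    synthetic-landscape generator so the full pipeline is testable
    without external spatial data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
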