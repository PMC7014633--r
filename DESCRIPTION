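Package: vectorops
Title: Transportation Network Analysis for Mosquito-Control Service Delivery
Version: 0.1.0
Authors@R:
    person("VectorOps", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Planning tools for municipal mosquito abatement programs that
    deliver larvicide and residual-spray services from a small number of
    deployment hubs over an urban road network. Provides service-area
    binning of neighborhoods by network driving distance, closest-facility
    routing with a capacitated trip and round-trip fuel cost model,
    weighted p-median location-allocation of candidate spray hubs (exact
    enumeration and Teitz-Bart vertex substitution), readers and writers
    for road networks and facilities as GeoJSON or CSV, and a seeded
    synthetic-city generator so the full pipeline is testable without
    restricted census or case data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
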