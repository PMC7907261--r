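Package: agrisk
Title: Agricultural Non-Point-Source Pollution Risk Mapping and
    Spatiotemporal Evolution Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Raster implementation of a three-dimensional
    ("Input-Translate-Output") multi-factor evaluation model for
    agricultural non-point-source pollution risk, together with the
    spatiotemporal analyses used to study its evolution: a three-epoch
    risk-grade transition matrix, quartic-kernel density surfaces of
    at-risk cells with equal-interval 10-grade zoning, and the local
    Getis-Ord Gi* hot/cold-spot statistic with z scores, p values and
    confidence bins. Twelve indicator layers are built from land use,
    terrain, rainfall erosivity, distance-to-water and per-zone
    agro-environmental statistics via reference-value normalization and
    Nemerow composite indices, then aggregated with expert weights into
    a composite risk score graded on a five-class scale. A seeded
    synthetic-landscape generator produces complete study regions with
    known ground truth (planted risk clusters, per-zone parameters) so
    the whole pipeline is testable without external data. Grids are
    read and written as ESRI ASCII rasters; zone statistics as CSV.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    Matrix,
    igraph,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
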