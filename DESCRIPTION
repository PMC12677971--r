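Package: bandapfz
Title: Fishing Season Indices and Neural-Network Potential Fishing Zones
    for Small Pelagic Fisheries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for seasonal analysis and habitat-based prediction of
    small pelagic catch rates, motivated by Indian mackerel (Rastrelliger
    spp.) purse-seine fisheries in the western Banda Sea.  Standardizes
    trip-level catches to catch per unit effort (CPUE), computes the
    Fishing Season Index (FSI) by ratio-to-moving-average seasonal
    decomposition with peak/fishing/regular/lean classification, trains a
    single-hidden-layer backpropagation neural network regressing CPUE on
    sea surface temperature, chlorophyll-a, salinity and current speed,
    quantifies predictor contributions by permutation importance and
    connection weights, and maps potential fishing zones from monthly
    gridded environmental fields.  A seeded synthetic-data generator with
    a known CPUE-environment response makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
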