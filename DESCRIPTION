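Package: qsar4d
Title: Receptor-Independent 4D-QSAR with Grid Cell Occupancy Descriptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Receptor-independent four-dimensional quantitative
    structure-activity relationship (4D-QSAR) analysis for a series of 54
    2-arylbenzothiophene (raloxifene) analogs acting as selective estrogen
    receptor modulators. Builds conformational ensemble profiles with a
    Metropolis torsional sampler, overlays them on a cubic lattice after
    three-point rigid alignment, computes normalized grid cell occupancy
    descriptors partitioned by interaction pharmacophore element classes,
    prunes the descriptor pool with three serial reduction filters, and
    searches descriptor subsets with a genetic algorithm scored by
    Friedman's lack-of-fit over partial least squares fits. Includes
    leave-one-out cross-validation, residual and outlier diagnostics, the
    five published benchmark equations with their activity tables as
    fixtures, and a synthetic-series generator with planted coefficients
    for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ChemmineR,
    mixOmics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
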