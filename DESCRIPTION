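Package: chiraflux
Title: Chiral Monoterpene Emission Analysis for Enclosed Mesocosm Drought
    Experiments
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for enantiomerically resolved monoterpene and
    isoprene emissions from a semi-enclosed rainforest mesocosm under
    progressive drought. Estimates the chamber air-exchange rate from SF6
    tracer decay and applies the leakage correction to volume mixing ratios,
    computes vapour pressure deficit, net ecosystem exchange and ecosystem
    assimilation from the chamber CO2 mass balance, derives 13C enrichment
    offsets from pulse-labelling isotope samples and classifies each
    compound's emission source (de novo vs storage pool), builds
    stage-resolved diel cycles with drought proxies, and forward-simulates a
    three-enzyme-group/two-reservoir emission model against a pooled
    light-and-temperature baseline. A seeded synthetic mesocosm generator
    provides ground-truth campaigns so every stage of the pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
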