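Package: wormQHTS
Title: Quantitative High-Throughput Screening Analysis for C. elegans
    Viability Assays
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for 384-well quantitative high-throughput
    screens (qHTS) of GFP-expressing Caenorhabditis elegans read by
    laser-scanning cytometry. Gates object-level cytometry events into
    per-well viability readouts (total GFP area, worm number), computes
    plate quality statistics (signal-to-background, signal-to-noise,
    Z-factor) from control wells, normalizes wells to the DMSO/levamisole
    control scale, assembles inter-plate titrations, fits four-parameter
    logistic dose-response curves, assigns qHTS curve classes and
    follow-up priorities, classifies COPAS flow events into life stages,
    and tests self-organizing-map chemotype clusters for potency
    enrichment. A seeded synthetic-screen generator produces
    ground-truth-annotated compound libraries, plate layouts, stage
    structured worm populations and event tables so every stage can be
    validated end to end without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Software, CellBasedAssays, Pharmacogenomics, QualityControl,
    Clustering
RoxygenNote: 7.3.3
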