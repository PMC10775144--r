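Package: capsidms
Title: Intact-Mass Identity Testing and PTM Monitoring for AAV Capsid Proteins
Version: 0.1.0
Authors@R:
    person("capsidms", "developers", email = "capsidms@example.org",
           role = c("aut", "cre"))
Description: Tools for rapid adeno-associated virus (AAV) serotype identity
    testing and capsid-protein proteoform monitoring from intact HILIC-FLR-MS
    runs. Builds serotype proteoform component libraries with theoretical
    average masses, deconvolves intact MS1 charge-state envelopes to neutral
    masses, matches deconvolved features to library components by retention
    time and mass tolerance, forms replicate consensus and calls the serotype,
    computes VP stoichiometry (copies of 60, ratios of 12) from fluorescence
    peak areas or extracted-ion-chromatogram areas, and quantifies site-level
    relative PTM abundance from peptide-mapping record tables. A seeded
    simulator generates synthetic HILIC-FLR-MS runs and peptide tables with
    known ground truth so every pipeline stage is testable without instrument
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
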