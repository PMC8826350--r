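Package: capa
Title: Feature-Driven Substructure Pattern Analysis for Multitarget
    Modulator Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computer-aided pattern analysis for multitarget modulator
    landscapes of ABC transporter (ABCB1/ABCC1/ABCG2) inhibitors.
    Classifies compounds from triple-target IC50 profiles into potency
    classes, builds binary compound-by-substructure distribution schemes
    with per-class percentage and ratio statistics, grades substructures
    on a two-axis point score into inner (potent) and outer (weak)
    multitarget modulator landscape groups, and runs a six-stage
    substructure-filter virtual-screening cascade that triages compound
    libraries toward the outer landscape. Ships a deterministic
    synthetic-data generator that plants substructures and
    class-conditional IC50 profiles with a full ground-truth ledger.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineOB,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
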