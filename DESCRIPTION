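Package: gemflux
Title: Genome-Scale Metabolic Model Reconstruction and Flux Balance Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based modelling toolkit for genome-scale metabolic
    networks (GEMs): SBML and tabular model I/O, flux balance analysis (FBA)
    with a built-in bounded-variable simplex solver, medium handling and
    carbon-source growth screening, biomass-equation construction from genome
    composition, maintenance-energy calibration from chemostat data (Pirt's
    law, NGAM and GAM fitting), GPR-aware single-gene essentiality screening,
    dynamic FBA for batch culture, homology-based draft reconstruction with
    gap-filling, and phenotype-microarray concordance scoring with
    phenotype-driven model refinement. Ships deterministic synthetic-fixture
    generators with analytically known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    xml2,
    jsonlite,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
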