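Package: rareassembly
Title: Assembly Process Inference for Abundant and Rare Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparing biogeographic patterns and community assembly
    processes of abundant and rare sub-communities in microbial (OTU-based)
    survey data. Implements partitioning of OTUs by relative abundance,
    occupancy and abundance-occupancy statistics, distance-decay regression,
    Levins niche breadth, abundance-based null models with the beta-deviation
    standardized effect size, Sloan's neutral community model, Mantel tests,
    multiple regression on distance matrices (MRM) with forward selection,
    distance-matrix variation partitioning and the environmental-selection to
    dispersal-limitation ratio (ESDR), plus a synthetic-data generator with
    known assembly regimes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
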