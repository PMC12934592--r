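Package: redoxmap
Title: Cross-Species Mapping and Classification of Redox-Regulated
    Protein Cysteines with Covalent-Ligand Engagement Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline for discovering functionally relevant,
    redox-regulated cysteines on proteins. Maps conserved cysteines
    between mouse and human orthologs by affine-gap global alignment,
    classifies each site as stable or dynamic from per-tissue oxidation
    stoichiometry (delta of condition means against a fixed threshold),
    annotates sites with domain intervals and protein-class membership
    into a compendium table, and scores proteome-wide covalent-ligand
    engagement of cysteines from TMT signal-to-noise tables (competition
    ratios, percent engagement, reproducible hit calling, selectivity
    and dose-response checks). A synthetic-data generator with planted
    ground truth makes every stage verifiable at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
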