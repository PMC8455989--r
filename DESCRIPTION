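Package: twocys
Title: Annotation, Classification and Phylogeny of Diatom 2-Cys Type III Metacaspases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style pipeline for discovering the diatom-specific
    "2-Cys" subtype of type III metacaspases from protein sequence
    collections. Detects the p20 catalytic domain by position-specific
    scoring against a seed alignment, finds the p10 domain with a
    three-anchor PROSITE-style pattern search, classifies metacaspase
    architecture (type I/II/III and metacaspase-like proteases), calls the
    regulatory cysteine pair homologous to PtMCA-IIIc C202/C259 by pairwise
    alignment to a reference, and builds bootstrapped neighbor-joining
    phylogenies of trimmed p20 domains. Supporting quantitation covers
    paired-guide CRISPR excision design with seed-sequence off-target
    screening, OxICAT cysteine oxidation-degree statistics (delta oxidation
    with a pooled two-sample t-test), fluorogenic AMC-release protease
    kinetics, and 2^-ddCt relative expression. Seeded synthetic-data
    generators plant ground truth for every stage so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
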