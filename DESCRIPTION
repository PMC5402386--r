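Package: resmutscan
Title: Prospective Prediction of Drug-Resistance Mutations in Small-Molecule Cancer-Therapy Targets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Connects cancer-type-specific trinucleotide mutational-signature
    likelihoods with structure-based resistance-phenotype prediction for
    small-molecule drug targets. Parses COSMIC-layout signature catalogs and
    per-cancer exposure profiles, enumerates the single-nucleotide-reachable
    missense mutations of a drug binding site (residues within a distance
    cutoff of the co-crystallized ligand), scores their likelihood, extracts
    sequence and structural features from wild-type/mutant complex pairs
    (surface areas, half-sphere exposure, hydrogen bonds, salt bridges,
    interaction fingerprints and more), trains four-class random-forest
    resistance classifiers with a precision-weighted Resistance Score, and
    screens candidate-compound panels into mutation-by-compound sensitivity
    maps. Includes a seeded synthetic-fixture generator so the whole pipeline
    is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    randomForest,
    pROC,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
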