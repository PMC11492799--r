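Package: phasekit
Title: Two-Task Prediction of Liquid-Liquid Phase Separation Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence-based prediction of liquid-liquid phase separation
    (LLPS) proteins and of their phase-separation mechanism (self-assembling
    PS-Self versus partner-dependent PS-Part). Provides readers for FASTA,
    AAIndex1, PSI-BLAST PSSM and HHsuite HHM profile formats; composition and
    physicochemical feature encoders (AAC, AAIndex-weighted composition,
    Shannon entropy, Kyte-Doolittle hydropathy, charge patterning); a hybrid
    convolutional / bidirectional-LSTM network with channel attention over
    evolutionary profile tensors for the LLPS-versus-non-LLPS task; a
    gradient-boosted-tree classifier with a three-step feature selection
    pipeline (extra-trees recursive feature elimination, split-count
    importance sweep, incremental forward selection) for the mechanism task;
    an in-silico saturation mutagenesis module for region-importance
    analysis; and synthetic-data generators so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    xgboost,
    ranger,
    randomForest,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
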