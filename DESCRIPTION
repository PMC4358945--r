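Package: pentaQSAR
Title: QSAR Screening of ACE-Inhibitory Pentapeptides from In Silico Protein Digestion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end in silico pipeline for discovering angiotensin
    I-converting enzyme (ACE) inhibitory pentapeptides from food proteins.
    Rule-based simulated proteolysis (ExPASy Peptide Cutter style pepsin and
    trypsin specificity tables) enumerates pentapeptide fragments from protein
    sequences such as the bovine hemoglobin subunits; peptides are described by
    ten molecular descriptors (fixture values from the reference literature set
    or computed from the sequence via OpenBabel); a three-layer feedforward
    network trained by Levenberg-Marquardt with validation-based early stopping
    maps min-max normalized descriptors to normalized pIC50; network outputs are
    denormalized back to predicted IC50 (microM) and candidates are ranked.
    Ships the 24-pentapeptide reference set with activities and descriptors,
    the seven hemoglobin-derived candidates, architecture-scan and
    restart-training utilities, structural-feature composition statistics and a
    synthetic-data generator for testing every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
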