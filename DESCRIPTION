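Package: aipfuse
Title: Anti-Inflammatory Peptide Prediction by Fused Random-Forest Encoders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies short peptides (1-25 residues) as anti-inflammatory or
    not by encoding each sequence with complementary feature sets -- k-spaced
    amino-acid-pair composition (KSAAP), per-position physicochemical indices
    (AAindex), the KSAAP construction applied to a position-specific scoring
    matrix (pKSAAP), and optional per-residue structural descriptors -- scoring
    each encoding with its own random forest, and fusing the per-encoder scores
    by a grid-searched convex combination. Decision thresholds are calibrated
    to target specificities so predictions can be reported at high, moderate
    and low confidence. Includes information-gain feature ranking, evaluation
    utilities (sensitivity, specificity, accuracy, MCC, ROC/AUC, stratified
    cross-validation), per-position residue-enrichment statistics, and a
    synthetic-data generator that emulates positional residue enrichment and
    matched profile/structure tables so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ranger,
    seqinr,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
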