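Package: virionpred
Title: Ensemble Prediction of Phage Virion Proteins from Evolutionary
    Profile Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies bacteriophage proteins as virion (structural) or
    nonvirion from evolutionary sequence profiles. Parses PSI-BLAST ASCII
    position-specific scoring matrices (PSSMs), derives five profile-based
    feature encodings (AAC-PSSM, PSSM composition, DPC-PSSM, AADP-PSSM,
    MEDP) plus four sequence-based comparison encodings (AAC, DPC, QSOrder,
    PAAC), handles class imbalance by undersampling the majority class into
    balanced subsets, trains one radial-basis-function support vector
    machine per subset with grid-searched cost and gamma, and integrates
    the per-feature ensembles by score averaging into a single calibrated
    predictor. Includes the five standard binary-classification metrics
    (sensitivity, specificity, accuracy, F-value, Matthews correlation
    coefficient), repeated stratified cross-validation and independent-test
    protocols, a sequence-similarity (BLAST hit) baseline classifier, and a
    synthetic profile generator with a tunable class signal for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    e1071,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
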