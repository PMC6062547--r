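Package: sulfenpred
Title: Prediction of Protein S-Sulfenylation Sites from Primary Sequence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts S-sulfenylation of protein cysteine residues from
    primary sequence alone. Extracts 21-residue cysteine-centred peptide
    windows (X-padded at protein termini), encodes them with five feature
    schemes (position-wise one-hot binary encoding, 14 AAindex
    physicochemical properties, k-spaced amino-acid pair counts, amino-acid
    composition, and 8 high-quality AAindex indices; 2,203 features in
    total), balances training classes by seeded random oversampling, and
    trains a radial-basis-function support-vector classifier. Evaluation
    utilities provide confusion-matrix metrics (accuracy, sensitivity,
    specificity, Matthews correlation coefficient), ROC curves with
    trapezoid AUC, stratified k-fold cross-validation with configurable
    oversampling placement, and per-feature ablation tables. A seeded
    synthetic fragment generator with tunable class separability allows the
    full pipeline to run without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    seqinr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
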