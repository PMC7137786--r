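Package: psbind
Title: Identification of Polystyrene-Binding Peptides with Composition
    Features and Support Vector Machines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Binary classification of short peptides as polystyrene-binding
    (PSBP) or not, from sequence alone. Peptide sets are curated (ambiguous
    or non-alphabetic characters, cross-class duplicates, generalized
    Jaccard redundancy), encoded as 420-dimensional weighted amino-acid and
    dipeptide composition vectors, ranked by one-way ANOVA F-scores, reduced
    by incremental feature selection with cross-validated accuracy, and
    classified by a grid-search-tuned radial-basis-function support vector
    machine. Includes five-fold cross-validated evaluation (sensitivity,
    specificity, accuracy, ROC AUC), feature-set composition reports, a
    synthetic benchmark generator with controllable residue enrichment, and
    a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
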