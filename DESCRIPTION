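Package: dpas
Title: Disease Peptide Anomaly Scoring with One-Class Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks candidate disease-associated peptides learned from
    positive-only data. Extracts a panel of sequence descriptors from
    peptides (amino-acid and dipeptide composition, reduced-alphabet
    grouped composition, physicochemical class composition, mean residue
    volume and hydrophobicity, Shannon entropy, repeated-residue content,
    and binary motif occurrence), fits one-class anomaly models (one-class
    SVM, isolation forest, autoencoder, and PCA reconstruction error)
    under a common scoring contract, normalizes and thresholds anomaly
    scores at a percentile, and fuses normalized anomaly scores with
    permutation-based feature importance into the Disease Peptide Anomaly
    Score (DPAS) used to rank peptides. Includes a seeded synthetic
    peptide generator with planted outliers, column-permutation synthetic
    negatives for positive-unlabeled evaluation, and a command-line
    interface over the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    seqinr,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
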