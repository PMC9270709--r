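Package: delirnlp
Title: Detecting Delirium Episodes in Unstructured Clinical Notes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting delirium episodes in
    free-text clinical notes. Extracts sentences containing delirium
    keywords, propagates labels from expert-authored "always pattern"
    regular expressions, acquires further labels through an active-learning
    loop (entropy uncertainty plus embedding-map diversity queries), trains
    three keyword-anchored three-class sentence classifiers (bag-of-n-grams
    linear, bidirectional recurrent, and self-attention models), evaluates
    them with micro/macro F1, normalized confusion matrices, one-vs-rest
    ROC/AUC and bootstrap confidence intervals, and aggregates sentence
    detections to patient-level indicators whose construct validity is
    quantified against other delirium indicators via the phi coefficient.
    Includes a synthetic clinical-note generator with known ground truth so
    every stage is testable without protected health information.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    e1071,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
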