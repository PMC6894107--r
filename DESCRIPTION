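Package: attrseq
Title: One-Step Attribute Detection for Clinical Concepts by Sequence Labeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Detects attributes of medical concepts (disorder modifiers,
    medication signatures, lab-test values) in annotated clinical text.
    Implements the concept-focused sequence (CFS) transformation, which turns
    attribute detection for a given target concept into a single sequence
    labeling problem, together with a target-aware Bi-LSTM-CRF tagger whose
    per-token input concatenates word, character-derived and concept-role-tag
    embeddings. Also provides the traditional two-step cascade (attribute
    named-entity recognition followed by per-type binary relation
    classification with either a linear margin classifier or a Bi-LSTM
    classifier with position embeddings), strict concept-aligned evaluation
    metrics with cross-validation, BRAT-style standoff readers and writers,
    and a seeded generator of synthetic clinical-style corpora for
    development and testing without access to restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    e1071,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
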