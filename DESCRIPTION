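Package: picosift
Title: Hybrid CRF and Rule-Based Extraction of PICO Sentences from Medical Abstracts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage pipeline for locating Population, Intervention and
    Outcome (PICO) sentences in medical abstracts. A feature-engineered
    linear-chain conditional random field labels sentences (coarse-grained),
    a weighted assessment step picks the most plausible sentence per PICO
    element per abstract, and a rule-based fallback stage recovers elements
    the statistical stage missed (fine-grained). Includes corpus input/output
    for a documented JSON/CSV schema, abbreviation-aware sentence
    segmentation, section-header normalization, lexicon-based semantic
    tagging, precision/recall/F evaluation with cross-validation, and a
    synthetic-corpus generator so the whole pipeline is testable without any
    external corpus.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
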