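Package: humtag
Title: Probabilistic Tagging of Human-Related Biomedical Citations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains and applies a probabilistic tagger that estimates, for a
    bibliographic citation record (title, abstract, authors, journal,
    pagination), the probability that the article concerns humans, using the
    curator-assigned MeSH "Humans" heading as the reference standard. Features
    are bag-of-n-grams and bibliographic feature classes; the classifier is a
    sparse linear support vector machine whose signed margins are mapped to
    calibrated probabilities by a monotone calibration step. Feature classes
    are chosen by forward selection under five iterations of two-fold
    cross-validation with an AUC-then-MCC improvement rule. Includes readers
    for PubMed/MEDLINE XML and a JSON-lines citation table, binary and
    probabilistic evaluation metrics (AUC, MCC, F1, Brier score, calibration
    curves), an extreme-disagreement audit workflow, and a synthetic citation
    generator with exact Bayes posteriors for validation without MEDLINE.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    stringi,
    utils,
    xml2
LinkingTo: Rcpp
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
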