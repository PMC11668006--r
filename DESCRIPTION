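Package: redactnames
Title: Automated Redaction of Person Names in Adverse Event Case Narratives
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: De-identification of free-text adverse event (pharmacovigilance)
    case narratives by detection and placeholder redaction of person names.
    Combines a hand-engineered rule classifier (salutation, label and title
    contexts) with a trainable transformer token classifier under an OR
    ensemble, applies a privacy-conservative decision threshold, and scores
    predictions in covering mode with token-level precision, recall, F1 and
    false-positive rate stratified by token length, plus narrative-level
    recall. Includes readers for JSONL standoff annotations and the i2b2 2014
    de-identification XML dialect, a regex-based candidate selector for
    enriching training corpora, a name-injection sensitivity protocol, and a
    synthetic annotated-narrative generator emulating spontaneous-report data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
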