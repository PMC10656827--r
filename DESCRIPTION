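Package: canscreen
Title: Rule-Based Screening of Clinical Notes for Child Abuse and Neglect
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for screening pediatric clinical notes for mentions of
    child abuse and neglect (CAN). Builds an expert-curated CAN lexicon from
    multi-round survey ratings, runs a rule-based annotation pipeline
    (sentence detection, tokenization, dictionary named-entity recognition
    over five CAN subtypes, negation scope detection, configurable
    false-positive exclusion rules, and low-specificity corroboration),
    classifies sentences and notes, summarizes results by note type and
    subtype, trains an n-gram support-vector sentence classifier, and
    evaluates precision with a two-reviewer adjudication workflow. A seeded
    synthetic clinical-note generator with gold annotations makes the whole
    pipeline testable without any protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    rlang,
    withr,
    jsonlite,
    yaml,
    Matrix,
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
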