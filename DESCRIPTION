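Package: firearmintent
Title: Classify Firearm Injury Intent from Free-Text Clinical Notes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid rule-based and machine-learning pipeline that assigns
    firearm-injury intent (accident, assault, legal intervention, self-harm,
    unknown) to cases built from free-text hospital records. Lexicon-driven
    term extraction with clinical context modifiers (negation, history,
    other-subject), dependency-relation extraction of shooter and person-shot
    roles, an expert rule engine emitting binary features, and a shallow
    gradient-boosted classifier, together with an evaluation harness
    (confusion matrices, per-class metrics, one-vs-rest ROC and
    precision-recall curves, ICD-code comparison) and a synthetic multi-note
    case generator so the whole pipeline is testable without protected
    health data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    jsonlite,
    ggplot2,
    generics,
    withr,
    xgboost,
    randomForest,
    nnet,
    e1071,
    caret,
    rpart,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
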