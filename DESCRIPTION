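Package: healthnewseval
Title: Criteria-Based Health News Quality Evaluation with Interpretable
    Sentence Highlighting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automates criteria-based quality assessment of health news
    articles (cost, harm and conflict-of-interest criteria) with TF-IDF
    document classifiers, and makes the verdicts interpretable at the
    sentence level through two visual-explanation pipelines: a hybrid
    highlighter that merges perturbation-based local surrogate (LIME-style)
    keyword attributions with curated keyword lists, and a typology
    highlighter driven by an evidence-sentence classifier trained on
    adjudicated annotations. Includes a seeded synthetic corpus generator
    with planted evidence sentences and confounders, repeated k-fold AUC
    evaluation with randomized hyperparameter search, highlighting-accuracy
    curves over the number of highlighted sentences, and threshold-based
    selection of the optimal highlighting window.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Matrix,
    glmnet,
    ranger,
    e1071,
    yaml,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
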