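Package: hfselect
Title: Hybrid Feature Selection with Hesitant-Fuzzy-Set Scoring for
    Clinical Outcome Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hybrid feature selection for tabular clinical cohorts with a
    binary outcome, built around a cross-validated random-forest classifier.
    Filter and embedded pre-selectors (variance threshold, ANOVA-F k-best,
    L1-penalised logistic regression, tree-ensemble importance) are ranked
    by a hesitant-fuzzy-set scoring system that rewards methods whose six
    evaluation criteria (accuracy, AUC, F-score, normalised Matthews
    correlation, precision, recall) agree with each other; the winning
    pre-selector's feature pool is then searched by sequential, floating
    and random wrapper algorithms. Includes a synthetic IVF/ICSI-like
    cohort generator with planted informative features for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    graphics,
    ranger,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
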