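Package: depstack
Title: Depressed-User Detection from Microblog Post Streams via Hybrid
    Feature Selection and Stacked Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Screens microblog-style social-media users for depression risk
    from their post streams. Extracts per-user textual features (part-of-speech
    proportions, emotion-lexicon rates, pronoun and negation/interrogative
    rates, post polarity proportions) and posting-behavior features (original/
    picture/location habits, 6-hour and weekday posting rhythms), selects
    features by fusing recursive-feature-elimination, extremely-randomized-tree
    and mutual-information importance weights, balances classes with SMOTE, and
    classifies with a two-level stacking ensemble (SVM, k-NN, Gaussian naive
    Bayes, lasso and ridge logistic base learners under a logistic
    meta-learner). Includes the full evaluation protocol (stratified splits,
    paired cross-validation, Friedman and Wilcoxon signed-rank comparisons) and
    a synthetic-corpus generator so the whole pipeline is testable without
    access to any social-media platform.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    glmnet,
    jsonlite,
    randomForest,
    ranger,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
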