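# depstack

Screening social-media users for depression risk from what and when they
post. `depstack` is an R implementation of a depressed-user detection
pipeline for microblog platforms: per-user feature engineering over post
streams, hybrid feature selection, SMOTE class balancing, a two-level
heterogeneous stacking classifier, and the full evaluation protocol
(stratified splits, paired cross-validation, Friedman and Wilcoxon
comparisons). It is aimed at mental-health informatics researchers who have
(or can license) labelled user post streams, and at methods researchers who
want a reproducible, fully synthetic test bed for this class of pipeline.

Real platform data cannot be redistributed, so the package ships a
synthetic-corpus generator that emulates the study conditions end to end —
two user classes at a 130:320 ratio whose post streams differ in lexicon
usage, posting rhythm, and habit flags — and every stage is exercised and
tested against it.

## The method

**Features.** Each user's post stream is reduced to 52 rate/proportion
features in two groups: *textual* (20 part-of-speech proportions, 7 emotion
lexicon rates, 6 pronoun-class rates, negation and interrogative rates per
1000 tokens, and the proportions of negative/neutral/positive posts) and
*posting behavior* (original/picture/location habit proportions, four 6-hour
posting bins, seven weekday proportions). Rates and proportions, never raw
counts, so heavy and light posters are comparable.

**Selection.** Three importance scorers each produce a normalized weight
vector over the `n` features: `W_r` from recursive feature elimination under
a random forest (wrapper), `W_e` from extremely-randomized-trees impurity
importance (embedded), and `W_m` from each feature's share of the total
feature–label mutual information (filter, nearest-neighbour estimator). The
fused weight is

```
W = W_r + W_e + W_m
```

and the 20% of features with the smallest `W` are dropped (52 → 42 under
the default schema).

**Classifier.** A stacking ensemble: five heterogeneous base learners —
RBF-kernel SVM, distance-weighted k-NN, Gaussian naive Bayes, lasso (LG1)
and ridge (LG2) logistic regression — are each fitted on K=5 folds of the
training set; their out-of-fold probabilities of the depressed class form a
five-column meta-feature matrix on which a binary logistic meta-learner is
trained. Out-of-fold construction guarantees no base learner ever scores a
sample it was trained on.

**Imbalance.** SMOTE synthesizes minority-class samples by random
interpolation between a minority point and one of its k=5 nearest minority
neighbours — applied to training data only, after the stratified 75/25
split.

**Evaluation.** Accuracy, precision, recall and F1 (depressed = positive),
paired 10-fold CV score matrices across methods, a tie-corrected Friedman
test and pairwise exact Wilcoxon signed-rank tests.

## Worked example

```r
library(depstack)

cfg    <- scenario_config()               # 130 depressed / 320 control users
corpus <- generate_corpus(cfg, seed = 42)
tab    <- build_feature_table(corpus$users, corpus$lexicons,
                              fallback_tagger(corpus$tag_map))
tab
#> <feature_table: 450 users x 52 features; 130 depressed / 320 control / 0 unlabelled>

sel <- fusion_select(tab, drop_fraction = 0.20, seed = 42)
sel$selection
#> <selection_result: 42 retained / 10 dropped (drop fraction 0.20)>
head(sel$selection$ranking[, c("feature", "w_fused", "rank")], 5)
#>               feature   w_fused rank
#> 1        pol_negative 0.3061881    1
#> 2         sw_negation 0.1996548    2
#> 3             emo_sad 0.1749809    3
#> 4 pron_first_singular 0.1619850    4
#> 5            time_h00 0.1463933    5

sp    <- stratified_split(tab$labels, 0.25, seed = 42)
bal   <- smote(sel$table$x[sp$train, ], sel$table$labels[sp$train], seed = 42)
model <- fit_stacking(bal$x, bal$y, k = 5, seed = 42)
pred  <- predict(model, sel$table$x[sp$test, ])
compute_metrics(sel$table$labels[sp$test], pred$label)
#> accuracy 0.9554 | precision 0.9355 | recall 0.9062 | F1 0.9206 (positive = 1)
```

The selector surfaces exactly the signals the generator plants — negative
polarity, negation words, sad-emotion words, first-person-singular pronouns
and small-hours posting lead the fused ranking — and the balanced stacking
model classifies the held-out 112 users (32 depressed, 80 control) with
0.9554 accuracy; precision/recall are for the depressed class.

`run_experiment()` produces the full method-comparison report (3 feature-set
models x 6 methods x balanced/unbalanced, with CV matrices and rank tests),
and `run_pipeline()` drives everything file-to-file; a thin command-line
wrapper lives at `inst/cli/depstack.R`.

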