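#' Evaluation protocol
#'
#' Stratified 75/25 train/test splits, confusion-matrix metrics (accuracy,
#' precision, recall, F1 with the depressed class positive by default),
#' paired 10-fold cross-validation score matrices, a tie-corrected Friedman
#' test across methods, pairwise exact Wilcoxon signed-rank tests, and the
#' report arithmetic used when tabulating balanced-vs-unbalanced accuracy
#' improvements in percentage points.
#'
#' @name evaluation
NULL

#' Stratified train/test split
#'
#' @param y 0/1 labels.
#' @param test_fraction Fraction of each class assigned to the test set
#'   (default 0.25); per-class test counts are within one sample of it.
#' @param seed Seed for the shuffle.
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
stratified_split <- function(y, test_fraction = 0.25, seed = 1L) {
  y <- as.integer(y)
  stopifnot(test_fraction > 0, test_fraction < 1)
  counts <- table(y)
  if (any(counts < 2L)) stop("each class needs at least 2 samples to split")
  test <- integer(0)
  with_seed(seed, {
    for (cl in sort(unique(y))) {
      idx <- which(y == cl)
      n_test <- round(length(idx) * test_fraction)
      n_test <- max(1L, min(length(idx) - 1L, n_test))
      test <- c(test, sample(idx, n_test))
    }
  })
  test <- sort(test)
  list(train = setdiff(seq_along(y), test), test = test)
}

#' Confusion-matrix metrics
#'
#' @param y_true,y_pred Equal-length 0/1 vectors.
#' @param positive_class Which label counts as positive (default 1,
#'   depressed).
#' @return Object of class `clf_metrics`: accuracy, precision, recall, f1
#'   and the TP/FP/TN/FN counts. Undefined precision/recall/F1 (empty
#'   denominator) is reported as 0 with a warning.
#' @export
compute_metrics <- function(y_true, y_pred, positive_class = 1L) {
  stopifnot(length(y_true) == length(y_pred))
  if (!length(y_true)) stop("empty input")
  tp <- sum(y_true == positive_class & y_pred == positive_class)
  fp <- sum(y_true != positive_class & y_pred == positive_class)
  tn <- sum(y_true != positive_class & y_pred != positive_class)
  fn <- sum(y_true == positive_class & y_pred != positive_class)
  precision <- if (tp + fp > 0) tp / (tp + fp) else {
    warning("no positive predictions; precision reported as 0"); 0
  }
  recall <- if (tp + fn > 0) tp / (tp + fn) else {
    warning("no positive truths; recall reported as 0"); 0
  }
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    warning("precision + recall = 0; F1 reported as 0"); 0
  }
  structure(
    list(accuracy = (tp + tn) / length(y_true), precision = precision,
         recall = recall, f1 = f1, tp = tp, fp = fp, tn = tn, fn = fn,
         positive_class = positive_class),
    class = "clf_metrics"
  )
}

#' @export
print.clf_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.4f | precision %.4f | recall %.4f | F1 %.4f (positive = %d)\n",
              x$accuracy, x$precision, x$recall, x$f1, x$positive_class))
  invisible(x)
}

#' F1 from precision and recall
#'
#' Harmonic mean `2pr/(p+r)`; in report mode the value is rounded half-even
#' to 4 decimals, the convention of published benchmark tables.
#'
#' @param p,r Precision and recall in `[0, 1]`, not both 0.
#' @param report Round to 4 decimals (default `TRUE`).
#' @return The F1 value.
#' @export
f1_from_pr <- function(p, r, report = TRUE) {
  stopifnot(all(p >= 0 & p <= 1), all(r >= 0 & r <= 1))
  if (any(p + r == 0)) stop("p + r must be positive")
  f <- 2 * p * r / (p + r)
  if (report) round(f, 4) else f
}

#' Accuracy improvement in percentage points
#'
#' `100 * (after - before)`, rounded to 2 decimals: the absolute
#' percentage-point convention used when tabulating balanced-vs-unbalanced
#' accuracy gains.
#'
#' @param after,before Accuracies in `[0, 1]`.
#' @return Improvement in percentage points.
#' @export
improvement_pp <- function(after, before) {
  stopifnot(all(after >= 0 & after <= 1), all(before >= 0 & before <= 1))
  round(100 * (after - before), 2)
}

#' Friedman test across methods (tie-corrected mid-ranks)
#'
#' Ranks methods within each evaluation unit (cross-validation fold), using
#' mid-ranks for ties, and computes the chi-square approximation
#' `(k-1) * sum_j (R_j - n(k+1)/2)^2 / (sum_ij r_ij^2 - n k (k+1)^2 / 4)`
#' with `k` methods and `n` units, which reduces to the classical statistic
#' when no ties occur. Degrees of freedom are `k - 1`.
#'
#' @param scores Numeric matrix, rows = units, columns = methods; no missing
#'   entries.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
friedman_test <- function(scores) {
  scores <- as.matrix(scores)
  n <- nrow(scores); k <- ncol(scores)
  if (k < 2L) stop("need at least 2 methods")
  if (n < 2L) stop("need at least 2 evaluation units")
  if (anyNA(scores)) stop("score matrix has missing entries")
  ranks <- t(apply(scores, 1, rank))  # mid-ranks for ties
  rj <- colSums(ranks)
  denom <- sum(ranks^2) - n * k * (k + 1)^2 / 4
  stat <- if (denom > 0) {
    (k - 1) * sum((rj - n * (k + 1) / 2)^2) / denom
  } else {
    0  # all methods tied in every unit
  }
  list(statistic = stat, df = k - 1L,
       p_value = stats::pchisq(stat, k - 1L, lower.tail = FALSE))
}

# Exact two-sided signed-rank p-value via the generating function of the
# rank-sum over sign assignments. Mid-ranks are doubled to integers so ties
# are handled exactly.
wilcoxon_exact_p <- function(ranks2, v2) {
  total <- sum(ranks2)
  probs <- c(1)  # distribution of 2*V over offsets 0..total
  for (r in ranks2) {
    shifted <- c(rep(0, r), probs)
    probs <- c(probs, rep(0, r)) / 2 + shifted / 2
  }
  vals <- 0:total
  p_le <- sum(probs[vals <= v2])
  p_ge <- sum(probs[vals >= v2])
  min(1, 2 * min(p_le, p_ge))
}

#' Pairwise Wilcoxon signed-rank tests across methods
#'
#' For every method pair, tests the paired per-unit score differences. Zero
#' differences are dropped; with 25 or fewer nonzero differences the exact
#' null distribution of the signed-rank sum is used (computed by convolution
#' over mid-ranks, so ties are handled exactly), otherwise the normal
#' approximation with tie correction. A pair with all-zero differences gets
#' p = 1 with a warning.
#'
#' @param scores Numeric matrix, rows = units, columns = methods.
#' @return Symmetric matrix of two-sided p-values with unit diagonal.
#' @export
wilcoxon_pairwise <- function(scores) {
  scores <- as.matrix(scores)
  k <- ncol(scores)
  nm <- colnames(scores) %||% paste0("method", seq_len(k))
  out <- matrix(1, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      d <- scores[, i] - scores[, j]
      d <- d[d != 0]
      if (!length(d)) {
        warning(sprintf("all differences zero for %s vs %s; p = 1",
                        nm[i], nm[j]))
        next
      }
      r <- rank(abs(d))
      v <- sum(r[d > 0])
      if (length(d) <= 25L) {
        p <- wilcoxon_exact_p(as.integer(round(2 * r)),
                              as.integer(round(2 * v)))
      } else {
        n <- length(d)
        mu <- n * (n + 1) / 4
        ties <- table(r)
        sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
          sum(ties^3 - ties) / 48
        z <- (v - mu) / sqrt(sigma2)
        p <- min(1, 2 * stats::pnorm(-abs(z)))
      }
      out[i, j] <- out[j, i] <- p
    }
  }
  out
}

methods_all <- function() c("svm", "nb", "knn", "lr_l1", "lr_l2", "stacking")

# Fit one method (single learner or stacking) on train and predict labels on
# test; single learners use grid-searched specs when provided.
fit_predict_method <- function(method, x_tr, y_tr, x_te, spec = NULL,
                               k_stack = 5L, seed = 1L) {
  if (method == "stacking") {
    model <- fit_stacking(x_tr, y_tr, k = k_stack, seed = seed)
    predict(model, x_te)$label
  } else {
    sp <- spec %||% default_learner_specs()[[method]]
    fit <- fit_base_learner(sp, x_tr, y_tr, seed = seed)
    as.integer(predict_prob(fit, x_te) >= 0.5)
  }
}

#' Run the full comparison experiment
#'
#' For each feature-set model (textual only, behavior only, both) and each
#' method (five single learners plus stacking): grid search on the training
#' split, fit, and test-set metrics — once on the imbalanced training data
#' and once after SMOTE balancing. For each feature-set model the same
#' 10-fold partition of the training set scores every method (paired
#' design), giving a fold x method accuracy matrix on which the Friedman
#' test and pairwise Wilcoxon tests are run.
#'
#' @param table A labelled [feature_table()] whose groups distinguish
#'   textual from behavior features.
#' @param seed Master seed (split, folds, fits, SMOTE).
#' @param test_fraction Test fraction of the stratified split.
#' @param cv_folds Folds of the paired score matrices and grid search.
#' @param k_stack Stacking fold count.
#' @param k_smote SMOTE neighbour count.
#' @param tune Run grid search for single learners (default `TRUE`).
#' @param positive_class Positive label for precision/recall/F1.
#' @param models Feature-set models to evaluate.
#' @param cv_models Feature-set models for which CV score matrices (and the
#'   rank tests) are computed; defaults to `"both"` only, the headline
#'   comparison.
#' @return Object of class `metrics_report`: `test_metrics` (data.frame),
#'   `improvement` (data.frame, full model), `cv_scores`, `friedman`,
#'   `wilcoxon` (per CV model).
#' @export
run_experiment <- function(table, seed = 1L, test_fraction = 0.25,
                           cv_folds = 10L, k_stack = 5L, k_smote = 5L,
                           tune = TRUE, positive_class = 1L,
                           models = c("textual", "behavior", "both"),
                           cv_models = "both") {
  stopifnot(inherits(table, "feature_table"))
  models <- match.arg(models, several.ok = TRUE)
  y <- table$labels
  if (anyNA(y)) stop("experiment requires fully labelled data")
  split <- stratified_split(y, test_fraction, seed = derive_seed(seed, "split"))

  rows <- list()
  cv_scores <- list(); friedman <- list(); wilcox <- list()
  for (model_name in models) {
    feats <- if (model_name == "both") colnames(table$x) else model_name
    sub <- subset_features(table, feats)
    x_tr <- sub$x[split$train, , drop = FALSE]; y_tr <- y[split$train]
    x_te <- sub$x[split$test, , drop = FALSE]; y_te <- y[split$test]

    bal <- smote(x_tr, y_tr, k_neighbors = k_smote,
                 seed = derive_seed(seed, "balance"))

    specs <- default_learner_specs()
    if (tune) {
      specs <- lapply(stats::setNames(nm = names(specs)), function(m) {
        grid_search(specs[[m]], x_tr, y_tr, cv_folds = cv_folds,
                    seed = derive_seed(seed, "train"))
      })
    }

    for (method in methods_all()) {
      for (balanced in c(FALSE, TRUE)) {
        xt <- if (balanced) bal$x else x_tr
        yt <- if (balanced) bal$y else y_tr
        pred <- fit_predict_method(method, xt, yt, x_te,
                                   spec = specs[[method]],
                                   k_stack = k_stack,
                                   seed = derive_seed(seed, "train"))
        m <- suppressWarnings(compute_metrics(y_te, pred, positive_class))
        rows[[length(rows) + 1L]] <- data.frame(
          model = model_name, method = method, balanced = balanced,
          accuracy = m$accuracy, precision = m$precision,
          recall = m$recall, f1 = m$f1,
          tp = m$tp, fp = m$fp, tn = m$tn, fn = m$fn,
          stringsAsFactors = FALSE
        )
      }
    }

    if (model_name %in% cv_models) {
      folds <- make_stratified_folds(y_tr, cv_folds,
                                     seed = derive_seed(seed, "evaluate"))
      mat <- matrix(NA_real_, cv_folds, length(methods_all()),
                    dimnames = list(NULL, methods_all()))
      for (f in seq_len(cv_folds)) {
        tr <- folds != f
        for (method in methods_all()) {
          pred <- fit_predict_method(method, x_tr[tr, , drop = FALSE],
                                     y_tr[tr], x_tr[!tr, , drop = FALSE],
                                     spec = specs[[method]],
                                     k_stack = k_stack,
                                     seed = derive_seed(seed, "train") + f)
          mat[f, method] <- mean(pred == y_tr[!tr])
        }
      }
      cv_scores[[model_name]] <- mat
      friedman[[model_name]] <- friedman_test(mat)
      wilcox[[model_name]] <- suppressWarnings(wilcoxon_pairwise(mat))
    }
  }
  test_metrics <- do.call(rbind, rows)

  imp <- NULL
  full_model <- if ("both" %in% models) "both" else models[[length(models)]]
  tm <- test_metrics[test_metrics$model == full_model, ]
  imp <- do.call(rbind, lapply(methods_all(), function(m) {
    before <- tm$accuracy[tm$method == m & !tm$balanced]
    after <- tm$accuracy[tm$method == m & tm$balanced]
    data.frame(method = m, acc_unbalanced = before, acc_balanced = after,
               improve_pp = improvement_pp(after, before),
               stringsAsFactors = FALSE)
  }))

  structure(
    list(test_metrics = test_metrics, improvement = imp,
         cv_scores = cv_scores, friedman = friedman, wilcoxon = wilcox,
         split = split, positive_class = positive_class, seed = seed),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("== test metrics ==\n")
  print(x$test_metrics[, c("model", "method", "balanced", "accuracy",
                           "precision", "recall", "f1")],
        digits = 4, row.names = FALSE)
  cat("\n== balanced vs unbalanced (full model) ==\n")
  print(x$improvement, digits = 4, row.names = FALSE)
  for (m in names(x$friedman)) {
    cat(sprintf("\nFriedman [%s]: chi2(%d) = %.3f, p = %.4g\n",
                m, x$friedman[[m]]$df, x$friedman[[m]]$statistic,
                x$friedman[[m]]$p_value))
  }
  invisible(x)
}

#' Write a metrics report to CSV files
#'
#' @param report A `metrics_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$test_metrics,
                   file.path(dir, "test_metrics.csv"), row.names = FALSE)
  utils::write.csv(report$improvement,
                   file.path(dir, "improvement.csv"), row.names = FALSE)
  for (m in names(report$cv_scores)) {
    utils::write.csv(report$cv_scores[[m]],
                     file.path(dir, sprintf("cv_scores_%s.csv", m)),
                     row.names = FALSE)
    utils::write.csv(report$wilcoxon[[m]],
                     file.path(dir, sprintf("wilcoxon_p_%s.csv", m)))
  }
  invisible(dir)
}
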