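#' Two-level heterogeneous stacking classifier
#'
#' Five base learners — RBF-kernel SVM, distance-weighted k-NN, Gaussian
#' naive Bayes, and lasso (L1) / ridge (L2) logistic regression — are each
#' fitted K times on K-fold splits of the training set. Every training sample
#' receives, from each learner, an out-of-fold (OOF) probability of being a
#' depressed user, predicted by the one fold-model that did not see that
#' sample. The resulting N x 5 meta-feature matrix, together with the true
#' labels, trains an L2-regularized binary logistic meta-learner, which makes
#' the final call. At test time each learner's meta-feature is the mean of
#' its K fold-models' probabilities.
#'
#' OOF construction is what keeps the meta-learner honest: a memorizing base
#' learner (say 1-NN) scores perfectly on samples it has seen but only
#' realistically on its held-out fold, and the meta-learner only ever sees
#' the held-out predictions.
#'
#' @name stack_ensemble
NULL

LEARNER_KINDS <- c("svm", "knn", "nb", "lr_l1", "lr_l2", "custom")

#' Specify a base learner
#'
#' @param kind One of `"svm"`, `"knn"`, `"nb"`, `"lr_l1"`, `"lr_l2"`, or
#'   `"custom"`.
#' @param params Named list of hyperparameters: `cost`/`gamma` (svm), `k`
#'   (knn), `lambda` (lr_l1/lr_l2). For `"custom"`, functions `fit(x, y)` and
#'   `predict_prob(model, x)`.
#' @param standardize Z-score features with fold-training statistics before
#'   fitting/predicting (default `TRUE`; ignored for `"custom"`).
#' @return An object of class `learner_spec`.
#' @export
learner_spec <- function(kind, params = list(), standardize = TRUE) {
  kind <- match.arg(kind, LEARNER_KINDS)
  structure(list(kind = kind, params = params, standardize = standardize),
            class = "learner_spec")
}

#' Default base-learner bank
#'
#' @return Named list of the five `learner_spec`s in meta-feature column
#'   order: `svm`, `knn`, `nb`, `lr_l1`, `lr_l2`.
#' @export
default_learner_specs <- function() {
  list(
    svm = learner_spec("svm", list(cost = 1, gamma = NULL)),
    knn = learner_spec("knn", list(k = 5)),
    nb = learner_spec("nb"),
    lr_l1 = learner_spec("lr_l1", list(lambda = 0.01)),
    lr_l2 = learner_spec("lr_l2", list(lambda = 0.01))
  )
}

#' Default (deliberately small) hyperparameter grids
#'
#' Grid points are enumerated with the first parameter varying fastest;
#' grid-search ties resolve to the earliest point in that order.
#'
#' @return Named list of per-learner grids (named lists of value vectors).
#' @export
default_grids <- function() {
  list(
    svm = list(cost = c(1, 10)),
    knn = list(k = c(5, 11)),
    nb = list(),
    lr_l1 = list(lambda = c(0.01, 0.001)),
    lr_l2 = list(lambda = c(0.01, 0.001))
  )
}

#' Fit one base learner
#'
#' @param spec A [learner_spec()].
#' @param x Numeric feature matrix.
#' @param y 0/1 labels.
#' @param seed Seed for stochastic fits.
#' @return An object of class `base_fit` usable with [predict_prob()].
#' @export
fit_base_learner <- function(spec, x, y, seed = 1L) {
  stopifnot(inherits(spec, "learner_spec"))
  x <- as.matrix(x)
  y <- as.integer(y)
  center <- scale_ <- NULL
  if (spec$standardize && spec$kind != "custom") {
    xs <- standardize(x)
    center <- attr(xs, "center"); scale_ <- attr(xs, "scale")
  } else {
    xs <- x
  }
  yf <- factor(y, levels = c(0L, 1L))
  p <- spec$params
  model <- with_seed(seed, switch(
    spec$kind,
    svm = e1071::svm(xs, yf, kernel = "radial",
                     cost = p$cost %||% 1,
                     gamma = p$gamma %||% (1 / ncol(xs)),
                     probability = TRUE),
    knn = list(x = xs, y = y, k = p$k %||% 5),
    nb = e1071::naiveBayes(data.frame(xs, check.names = FALSE), yf),
    lr_l1 = glmnet_fit(xs, yf, alpha = 1, lambda = p$lambda %||% 0.01),
    lr_l2 = glmnet_fit(xs, yf, alpha = 0, lambda = p$lambda %||% 0.01),
    custom = p$fit(x, y)
  ))
  structure(list(spec = spec, model = model, center = center,
                 scale = scale_, n_features = ncol(x),
                 feature_names = colnames(x)),
            class = "base_fit")
}

glmnet_fit <- function(xs, yf, alpha, lambda) {
  # decreasing path ending at the requested lambda gives a stable exact fit
  fit <- glmnet::glmnet(xs, yf, family = "binomial", alpha = alpha,
                        lambda = lambda * c(100, 10, 1),
                        standardize = FALSE)
  list(fit = fit, lambda = lambda)
}

#' Positive-class probability from a fitted base learner
#'
#' @param fit A `base_fit`.
#' @param x New data (same features as at fit time).
#' @return Numeric vector of probabilities of class 1.
#' @export
predict_prob <- function(fit, x) {
  stopifnot(inherits(fit, "base_fit"))
  x <- as.matrix(x)
  if (ncol(x) != fit$n_features) {
    stop(sprintf("feature-count mismatch: model expects %d, got %d",
                 fit$n_features, ncol(x)))
  }
  spec <- fit$spec
  xs <- if (!is.null(fit$center)) {
    standardize(x, fit$center, fit$scale)
  } else {
    x
  }
  pr <- switch(
    spec$kind,
    svm = {
      pred <- stats::predict(fit$model, xs, probability = TRUE)
      attr(pred, "probabilities")[, "1"]
    },
    knn = knn_prob(fit$model, xs),
    nb = stats::predict(fit$model, data.frame(xs, check.names = FALSE),
                        type = "raw", eps = 1e-9, threshold = 1e-3)[, "1"],
    lr_l1 = ,
    lr_l2 = as.numeric(stats::predict(fit$model$fit, xs, type = "response",
                                      s = fit$model$lambda)),
    custom = spec$params$predict_prob(fit$model, x)
  )
  pr <- as.numeric(pr)
  pr[!is.finite(pr)] <- 0.5  # degenerate densities (zero within-class var)
  pmin(pmax(pr, 0), 1)
}

# distance-weighted k-NN vote probabilities
knn_prob <- function(model, xnew) {
  vapply(seq_len(nrow(xnew)), function(i) {
    d <- sqrt(colSums((t(model$x) - xnew[i, ])^2))
    nn <- order(d)[seq_len(min(model$k, length(d)))]
    w <- 1 / (d[nn] + 1e-6)
    sum(w * (model$y[nn] == 1L)) / sum(w)
  }, 0)
}

#' Stratified fold assignment
#'
#' @param y 0/1 labels.
#' @param k Fold count.
#' @param seed Seed for the shuffle.
#' @return Integer vector of fold ids in `1..k`, one per sample, with class
#'   proportions balanced across folds.
#' @export
make_stratified_folds <- function(y, k, seed = 1L) {
  y <- as.integer(y)
  counts <- table(y)
  if (any(counts < k)) {
    stop("cannot stratify: a class has fewer samples than folds")
  }
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

#' Grid search for one learner by stratified cross-validated accuracy
#'
#' Evaluates every grid point with the same stratified `cv_folds`-fold split
#' and returns the spec updated with the point of maximal mean accuracy.
#' Ties resolve to the earliest point in canonical grid order (first
#' parameter varying fastest).
#'
#' @param spec A [learner_spec()].
#' @param x,y Training data.
#' @param grid Named list of parameter value vectors; empty grid returns
#'   `spec` unchanged.
#' @param cv_folds Fold count (default 10).
#' @param seed Seed for fold assignment and fits.
#' @return The winning `learner_spec`, with attributes `cv_accuracy` (best
#'   mean accuracy) and `cv_table` (accuracy per grid point).
#' @export
grid_search <- function(spec, x, y, grid = default_grids()[[spec$kind]],
                        cv_folds = 10L, seed = 1L) {
  if (is.null(grid) || !length(grid)) return(spec)
  combos <- do.call(expand.grid,
                    c(grid, list(KEEP.OUT.ATTRS = FALSE,
                                 stringsAsFactors = FALSE)))
  folds <- make_stratified_folds(y, cv_folds, seed = seed)
  acc <- vapply(seq_len(nrow(combos)), function(i) {
    sp <- spec
    sp$params[names(combos)] <- as.list(combos[i, , drop = FALSE])
    mean(vapply(seq_len(cv_folds), function(f) {
      fit <- fit_base_learner(sp, x[folds != f, , drop = FALSE],
                              y[folds != f], seed = seed + f)
      mean((predict_prob(fit, x[folds == f, , drop = FALSE]) >= 0.5) ==
             (y[folds == f] == 1L))
    }, 0))
  }, 0)
  best <- which.max(acc)  # which.max takes the first maximum: canonical tie rule
  out <- spec
  out$params[names(combos)] <- as.list(combos[best, , drop = FALSE])
  attr(out, "cv_accuracy") <- acc[best]
  attr(out, "cv_table") <- cbind(combos, accuracy = acc)
  out
}

#' Fit the two-level stacking model
#'
#' @param x Numeric feature matrix (training).
#' @param y 0/1 labels.
#' @param specs Named list of base-learner specs (order fixes meta-feature
#'   columns); default [default_learner_specs()].
#' @param k Stacking fold count (default 5).
#' @param seed Seed: drives fold assignment and all stochastic fits.
#' @param folds Optional explicit fold assignment (integer vector in
#'   `1..k`), overriding the seeded stratified assignment.
#' @param meta_lambda Ridge penalty of the logistic meta-learner.
#' @param threshold Decision threshold on the meta probability (label 1 when
#'   probability is greater than or equal to it).
#' @return An object of class `stacking_model`.
#' @export
fit_stacking <- function(x, y, specs = default_learner_specs(), k = 5L,
                         seed = 1L, folds = NULL, meta_lambda = 0.01,
                         threshold = 0.5) {
  x <- as.matrix(x)
  y <- as.integer(y)
  n <- nrow(x)
  stopifnot(n >= 2L * k, length(y) == n)
  if (is.null(folds)) folds <- make_stratified_folds(y, k, seed = seed)
  stopifnot(length(folds) == n, all(folds %in% seq_len(k)))

  oof <- matrix(NA_real_, n, length(specs),
                dimnames = list(NULL, names(specs)))
  fold_models <- lapply(specs, function(s) vector("list", k))
  for (j in seq_along(specs)) {
    for (f in seq_len(k)) {
      tr <- folds != f
      fit <- tryCatch(
        fit_base_learner(specs[[j]], x[tr, , drop = FALSE], y[tr],
                         seed = seed + 131 * j + f),
        error = function(e) stop(sprintf(
          "base learner '%s' failed on fold %d: %s",
          names(specs)[j], f, conditionMessage(e)), call. = FALSE))
      fold_models[[j]][[f]] <- fit
      oof[!tr, j] <- predict_prob(fit, x[!tr, , drop = FALSE])
    }
  }
  stopifnot(!anyNA(oof))
  meta <- glmnet_fit(oof, factor(y, levels = c(0L, 1L)), alpha = 0,
                     lambda = meta_lambda)
  structure(
    list(k = k, folds = folds, specs = specs, fold_models = fold_models,
         meta = meta, oof = oof, y = y, threshold = threshold,
         feature_names = colnames(x), n_features = ncol(x)),
    class = "stacking_model"
  )
}

#' @export
print.stacking_model <- function(x, ...) {
  cat(sprintf("<stacking_model: %d base learners x %d folds, %d features, threshold %.2f>\n",
              length(x$specs), x$k, x$n_features, x$threshold))
  invisible(x)
}

#' Meta-feature matrix for new samples
#'
#' One column per base learner, holding the mean positive-class probability
#' over that learner's K fold-models.
#'
#' @param model A fitted `stacking_model`.
#' @param x_new New feature matrix.
#' @return Numeric matrix, rows = samples, columns = base learners; all
#'   entries in `[0, 1]`.
#' @export
meta_features <- function(model, x_new) {
  stopifnot(inherits(model, "stacking_model"))
  x_new <- as.matrix(x_new)
  if (ncol(x_new) != model$n_features) {
    stop(sprintf("feature-count mismatch: model expects %d, got %d",
                 model$n_features, ncol(x_new)))
  }
  cols <- lapply(seq_along(model$specs), function(j) {
    per_fold <- vapply(model$fold_models[[j]],
                       function(fm) predict_prob(fm, x_new),
                       numeric(nrow(x_new)))
    rowMeans(matrix(per_fold, nrow = nrow(x_new)))
  })
  out <- do.call(cbind, cols)
  colnames(out) <- names(model$specs)
  out
}

#' Predict with a stacking model
#'
#' @param object A fitted `stacking_model`.
#' @param x_new New feature matrix.
#' @param threshold Decision threshold; defaults to the model's. A sample is
#'   labelled 1 when its meta probability is `>=` the threshold.
#' @param ... Unused.
#' @return data.frame with `probability` and `label` per sample.
#' @export
predict.stacking_model <- function(object, x_new,
                                   threshold = object$threshold, ...) {
  mf <- meta_features(object, x_new)
  pr <- as.numeric(stats::predict(object$meta$fit, mf, type = "response",
                                  s = object$meta$lambda))
  data.frame(probability = pr, label = as.integer(pr >= threshold))
}
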