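#' Hybrid (wrapper + embedded + filter) feature selection
#'
#' Three importance scorers produce per-feature weight vectors that each sum
#' to one: recursive feature elimination under a random-forest scorer
#' (wrapper), impurity importances of an extremely-randomized-trees ensemble
#' (embedded), and normalized mutual information between each feature and the
#' label (filter). Their element-wise sum `W = Wr + We + Wm` ranks the
#' features, and the bottom fraction (default 20%) is dropped. Normalizing
#' all three components before fusion makes rank-derived, impurity-derived
#' and information-derived scores commensurable.
#'
#' All scorers see z-scored copies of the data; mutual information and tree
#' importances are scale-invariant, and standardizing keeps the wrapper's
#' forest on the same footing.
#'
#' @name fusion_select
NULL

new_weight_vector <- function(feature_names, weights, source) {
  weights <- as.numeric(weights)
  stopifnot(length(weights) == length(feature_names), all(weights >= 0))
  s <- sum(weights)
  weights <- if (s > 0) weights / s else rep(1 / length(weights),
                                             length(weights))
  structure(
    list(feature_names = feature_names,
         weights = stats::setNames(weights, feature_names),
         source = source),
    class = "weight_vector"
  )
}

#' @export
print.weight_vector <- function(x, ...) {
  cat(sprintf("<weight_vector [%s]: %d features, top = %s>\n", x$source,
              length(x$weights), names(sort(x$weights, decreasing = TRUE))[1]))
  invisible(x)
}

check_xy <- function(x, y) {
  x <- as.matrix(x)
  if (is.null(colnames(x)) || any(!nzchar(colnames(x)))) {
    auto <- paste0("f", seq_len(ncol(x)))
    if (is.null(colnames(x))) colnames(x) <- auto
    colnames(x)[!nzchar(colnames(x))] <- auto[!nzchar(colnames(x))]
  }
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("y must contain both classes")
  stopifnot(nrow(x) == length(y), ncol(x) >= 2L)
  list(x = x, y = y)
}

#' Wrapper weights: recursive feature elimination under a random forest
#'
#' Repeatedly fits a random forest and removes the feature with the smallest
#' impurity importance until one feature remains. The elimination order is
#' mapped linearly to weights: the last survivor (rank 1) gets weight
#' proportional to `n`, the first feature eliminated (rank `n`) gets 1;
#' weights are normalized to sum to one.
#'
#' @param x Numeric feature matrix.
#' @param y 0/1 labels.
#' @param seed Seed for the forests.
#' @param ntree Trees per forest fit (the wrapper fits `n - 1` forests).
#' @return A `weight_vector` with `source = "rfe"`.
#' @export
rfe_weights <- function(x, y, seed = 1L, ntree = 100L) {
  d <- check_xy(x, y)
  xs <- standardize(d$x)
  yf <- factor(d$y, levels = c(0L, 1L))
  n <- ncol(xs)
  rank <- stats::setNames(integer(n), colnames(xs))
  remaining <- colnames(xs)
  with_seed(seed, {
    step <- n
    while (length(remaining) > 1L) {
      fit <- randomForest::randomForest(xs[, remaining, drop = FALSE], yf,
                                        ntree = ntree)
      imp <- fit$importance[, "MeanDecreaseGini"]
      # ties: drop the later schema feature first, so earlier ones survive
      ord <- order(imp, -match(remaining, colnames(xs)))
      worst <- remaining[ord[1L]]
      rank[worst] <- step
      step <- step - 1L
      remaining <- setdiff(remaining, worst)
    }
    rank[remaining] <- 1L
  })
  new_weight_vector(colnames(xs), n - rank + 1L, "rfe")
}

#' Embedded weights: extremely-randomized-trees impurity importance
#'
#' Mean impurity-decrease importances from an extra-trees ensemble
#' (randomized split thresholds, no bootstrap), normalized to sum to one.
#'
#' @inheritParams rfe_weights
#' @param num_trees Ensemble size (at least 100).
#' @return A `weight_vector` with `source = "extra_trees"`.
#' @export
tree_weights <- function(x, y, seed = 1L, num_trees = 200L) {
  d <- check_xy(x, y)
  stopifnot(num_trees >= 100L)
  xs <- standardize(d$x)
  df <- data.frame(xs, check.names = FALSE)
  df$.y <- factor(d$y, levels = c(0L, 1L))
  fit <- ranger::ranger(
    dependent.variable.name = ".y", data = df,
    num.trees = num_trees, splitrule = "extratrees", num.random.splits = 1L,
    importance = "impurity", replace = FALSE, sample.fraction = 1,
    seed = as.integer(seed)
  )
  imp <- pmax(fit$variable.importance[colnames(xs)], 0)
  new_weight_vector(colnames(xs), imp, "extra_trees")
}

# Nearest-neighbour mutual information between one continuous feature and a
# discrete label (Ross-type estimator, Chebyshev distance in 1-D). A tiny
# deterministic jitter breaks ties, as customary for k-NN MI on data with
# repeated values.
mi_continuous_discrete <- function(x, y, k = 3L, seed = 0L) {
  n <- length(x)
  x <- as.numeric(x)
  jit_scale <- 1e-10 * max(mean(abs(x)), 1)
  x <- x + with_seed(seed, stats::rnorm(n)) * jit_scale
  classes <- unique(y)
  r <- numeric(n)  # distance to the k-th same-class neighbour
  kk <- integer(n)
  for (cl in classes) {
    idx <- which(y == cl)
    nc <- length(idx)
    if (nc < 2L) return(0)
    k_c <- min(k, nc - 1L)
    o <- order(x[idx])
    xv <- x[idx][o]
    for (j in seq_len(nc)) {
      # k-th nearest same-class neighbour lies within k sorted positions
      win <- xv[max(1L, j - k_c):min(nc, j + k_c)]
      dists <- sort(abs(win - xv[j]))[-1L]  # drop self
      r[idx[o[j]]] <- dists[k_c]
      kk[idx[o[j]]] <- k_c
    }
  }
  ord <- sort(x)
  m <- vapply(seq_len(n), function(i) {
    # points within radius r[i] of x[i] (boundary included), excluding self
    lo <- x[i] - r[i]; hi <- x[i] + r[i]
    sum(ord >= lo & ord <= hi) - 1L
  }, 0L)
  m <- pmax(m, 1L)
  nc <- vapply(y, function(cl) sum(y == cl), 0L)
  mi <- digamma(n) - mean(digamma(nc)) + mean(digamma(kk)) - mean(digamma(m))
  max(mi, 0)
}

#' Filter weights: normalized mutual information with the label
#'
#' Estimates the mutual information between each (continuous) feature and the
#' binary label with a nearest-neighbour estimator (`k = 3`), clamps
#' estimates at zero and divides by their sum, so the weights are each
#' feature's share of the total mutual information.
#'
#' @inheritParams rfe_weights
#' @param k Neighbour count of the estimator.
#' @return A `weight_vector` with `source = "mutual_info"`. If every estimate
#'   is zero the weights fall back to uniform with a warning.
#' @export
mi_weights <- function(x, y, k = 3L, seed = 0L) {
  d <- check_xy(x, y)
  xs <- standardize(d$x)
  mi <- vapply(seq_len(ncol(xs)), function(j) {
    mi_continuous_discrete(xs[, j], d$y, k = k, seed = seed + j)
  }, 0)
  if (all(mi == 0)) warning("all mutual-information estimates are zero; using uniform weights")
  new_weight_vector(colnames(xs), mi, "mutual_info")
}

#' Fuse the three weight vectors
#'
#' Element-wise sum `W = Wr + We + Wm` over identically ordered feature
#' lists. Since each component sums to one, the fused weights sum to three.
#'
#' @param wr,we,wm `weight_vector`s from [rfe_weights()], [tree_weights()]
#'   and [mi_weights()] (any order of sources is accepted but names must
#'   match positionally).
#' @return An object of class `fused_weights` with the fused vector and the
#'   per-component breakdown.
#' @export
fuse_weights <- function(wr, we, wm) {
  comps <- list(wr, we, wm)
  nm <- wr$feature_names
  for (w in comps) {
    if (!identical(w$feature_names, nm)) {
      stop("weight vectors disagree on feature names/order; refusing to realign")
    }
  }
  fused <- wr$weights + we$weights + wm$weights
  structure(
    list(feature_names = nm, fused = fused,
         components = list(rfe = wr$weights, extra_trees = we$weights,
                           mutual_info = wm$weights)),
    class = "fused_weights"
  )
}

#' @export
print.fused_weights <- function(x, ...) {
  cat(sprintf("<fused_weights: %d features, sum = %.6f>\n",
              length(x$fused), sum(x$fused)))
  invisible(x)
}

#' Drop the lowest-weight fraction of features
#'
#' Removes the `floor(drop_fraction * n)` features with the smallest fused
#' weights. Ties are broken deterministically by dropping the feature with
#' the higher schema index (earlier-declared features survive). Retained
#' features keep their original schema order.
#'
#' @param fused A `fused_weights` object.
#' @param drop_fraction Fraction of features to drop, in `[0, 1)`;
#'   default 0.20.
#' @return An object of class `selection_result` with `retained`, `dropped`,
#'   `drop_fraction` and the fused `ranking` (a data.frame sorted from
#'   heaviest to lightest).
#' @export
select_features <- function(fused, drop_fraction = 0.20) {
  stopifnot(inherits(fused, "fused_weights"))
  if (drop_fraction < 0 || drop_fraction >= 1) {
    stop("drop_fraction must be in [0, 1)")
  }
  n <- length(fused$fused)
  n_drop <- floor(drop_fraction * n)
  w <- unname(fused$fused)
  # ascending weight; among ties, larger schema index first (dropped first)
  ord <- order(w, -seq_len(n))
  drop_idx <- if (n_drop > 0) ord[seq_len(n_drop)] else integer(0)
  retained <- fused$feature_names[sort(setdiff(seq_len(n), drop_idx))]
  dropped <- fused$feature_names[sort(drop_idx)]
  rank_ord <- rev(ord)  # heaviest first
  ranking <- data.frame(
    feature = fused$feature_names[rank_ord],
    w_rfe = unname(fused$components$rfe[rank_ord]),
    w_extra_trees = unname(fused$components$extra_trees[rank_ord]),
    w_mutual_info = unname(fused$components$mutual_info[rank_ord]),
    w_fused = w[rank_ord],
    rank = seq_len(n),
    retained = !fused$feature_names[rank_ord] %in% dropped,
    stringsAsFactors = FALSE
  )
  structure(
    list(retained = retained, dropped = dropped,
         drop_fraction = drop_fraction, ranking = ranking),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result: %d retained / %d dropped (drop fraction %.2f)>\n",
              length(x$retained), length(x$dropped), x$drop_fraction))
  invisible(x)
}

#' One-call hybrid selection on a feature table
#'
#' Computes the three weight vectors on the table's labelled rows, fuses
#' them and drops the bottom fraction.
#'
#' @param table A labelled [feature_table()].
#' @param drop_fraction Fraction of features to drop (default 0.20).
#' @param seed Seed shared by the stochastic scorers.
#' @return A list with the `selection_result` (`selection`), the
#'   `fused_weights` (`weights`) and the reduced `feature_table` (`table`).
#' @export
fusion_select <- function(table, drop_fraction = 0.20, seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  lab <- !is.na(table$labels)
  x <- table$x[lab, , drop = FALSE]
  y <- table$labels[lab]
  wr <- rfe_weights(x, y, seed = seed)
  we <- tree_weights(x, y, seed = seed)
  wm <- mi_weights(x, y, seed = seed)
  fused <- fuse_weights(wr, we, wm)
  sel <- select_features(fused, drop_fraction)
  list(selection = sel, weights = fused,
       table = subset_features(table, sel$retained))
}
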