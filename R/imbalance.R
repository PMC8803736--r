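#' SMOTE: synthetic minority oversampling
#'
#' Balances a training set by synthesizing minority-class samples. For each
#' synthetic sample, a minority point `x_i` is drawn, one of its `k` nearest
#' minority-class neighbours `x_z` is drawn, and the new point is the random
#' interpolation `x_i + u * (x_z - x_i)` with `u ~ Uniform(0, 1)`. Every
#' synthetic point therefore lies on a segment between two minority samples,
#' hence inside the minority class's convex hull. Original rows (both
#' classes) pass through unchanged.
#'
#' Oversampling must happen strictly after the train/test split, on training
#' data only — balancing before splitting leaks synthetic copies of test
#' neighbourhood structure into training.
#'
#' @param x Numeric feature matrix.
#' @param y 0/1 labels (either class may be the minority).
#' @param k_neighbors Neighbour count (default 5); must be smaller than the
#'   minority class size.
#' @param ratio Target minority:majority ratio (default 1 = fully balanced).
#' @param seed Seed; fixed seed gives bit-identical output.
#' @return List with the augmented `x`, `y`, and `synthetic` (logical flag
#'   per row, `TRUE` for generated rows, appended after the originals).
#' @export
smote <- function(x, y, k_neighbors = 5L, ratio = 1, seed = 1L) {
  x <- as.matrix(x)
  y <- as.integer(y)
  stopifnot(nrow(x) == length(y), k_neighbors >= 1L, ratio > 0)
  counts <- table(factor(y, levels = c(0L, 1L)))
  minority <- if (counts[["1"]] <= counts[["0"]]) 1L else 0L
  min_idx <- which(y == minority)
  n_min <- length(min_idx)
  n_maj <- length(y) - n_min
  if (n_min <= k_neighbors) {
    stop(sprintf(
      "minority class has %d samples but k_neighbors = %d; use a smaller k",
      n_min, k_neighbors))
  }
  n_new <- max(0L, as.integer(round(ratio * n_maj)) - n_min)
  if (n_new == 0L) {
    return(list(x = x, y = y, synthetic = rep(FALSE, nrow(x))))
  }

  xm <- x[min_idx, , drop = FALSE]
  d <- as.matrix(stats::dist(xm))
  diag(d) <- Inf
  # k nearest minority neighbours of each minority sample
  nn <- t(apply(d, 1, function(row) order(row)[seq_len(k_neighbors)]))

  synth <- with_seed(seed, {
    base_i <- sample.int(n_min, n_new, replace = TRUE)
    pick <- sample.int(k_neighbors, n_new, replace = TRUE)
    u <- stats::runif(n_new)
    xi <- xm[base_i, , drop = FALSE]
    xz <- xm[nn[cbind(base_i, pick)], , drop = FALSE]
    xi + u * (xz - xi)
  })
  rownames(synth) <- sprintf("synthetic_%04d", seq_len(n_new))
  list(
    x = rbind(x, synth),
    y = c(y, rep(minority, n_new)),
    synthetic = c(rep(FALSE, nrow(x)), rep(TRUE, n_new))
  )
}

#' SMOTE applied to a feature table
#'
#' @param table A labelled [feature_table()].
#' @inheritParams smote
#' @return A balanced `feature_table` (synthetic users get generated ids).
#' @export
balance_table <- function(table, k_neighbors = 5L, ratio = 1, seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  if (anyNA(table$labels)) stop("all rows must be labelled before balancing")
  out <- smote(table$x, table$labels, k_neighbors, ratio, seed)
  ids <- c(table$user_ids,
           sprintf("synthetic_%04d", seq_len(sum(out$synthetic))))
  feature_table(out$x, labels = out$y, user_ids = ids, groups = table$groups)
}
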