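test_that("rfe_weights maps elimination order linearly to weights", {
  # two features: one separates the classes perfectly, one is pure noise,
  # so the elimination order is forced and weights must be (2/3, 1/3)
  set.seed(10)
  n <- 60
  y <- rep(c(0L, 1L), each = n / 2)
  x <- cbind(signal = y + rnorm(n, sd = 0.05), noise = rnorm(n))
  w <- rfe_weights(x, y, seed = 1)
  expect_equal(unname(w$weights), c(2 / 3, 1 / 3))
  expect_equal(sum(w$weights), 1, tolerance = 1e-9)

  # identical copies: whatever the tie order, weights still sum to 1
  xc <- cbind(a = x[, 1], b = x[, 1], c = x[, 1])
  expect_equal(sum(rfe_weights(xc, y, seed = 2)$weights), 1, tolerance = 1e-9)

  expect_error(rfe_weights(x, rep(1L, n)), "both classes")
})

test_that("rfe_weights ranks an informative feature on top across seeds", {
  set.seed(11)
  n <- 150
  y <- rep(c(0L, 1L), each = n / 2)
  hits <- 0
  for (s in 1:20) {
    set.seed(100 + s)
    x <- cbind(matrix(rnorm(n * 4), n, 4), inf = y * 2 + rnorm(n, sd = 0.5))
    colnames(x) <- paste0("f", 1:5)
    w <- rfe_weights(x, y, seed = s, ntree = 50)
    hits <- hits + (names(which.max(w$weights)) == "f5")
  }
  expect_gte(hits, 18)  # >= 90% of 20 seeds
})

test_that("tree_weights: near-uniform on noise, dominant on a label copy", {
  n <- 500
  y <- rep(c(0L, 1L), each = n / 2)
  ratios <- vapply(1:10, function(s) {
    set.seed(200 + s)
    x <- matrix(rnorm(n * 5), n, 5)
    w <- tree_weights(x, y, seed = s)$weights
    max(w) / min(w)
  }, 0)
  expect_lt(mean(ratios), 3)

  set.seed(3)
  x <- cbind(copy = as.numeric(y), matrix(rnorm(n * 4), n, 4))
  w <- tree_weights(x, y, seed = 4)
  expect_gt(unname(w$weights[["copy"]]), 0.5)
  expect_equal(sum(w$weights), 1, tolerance = 1e-9)
})

test_that("mi_weights: label copy dominates, independent features near uniform", {
  n <- 400
  y <- rep(c(0L, 1L), each = n / 2)
  set.seed(5)
  x <- cbind(copy = as.numeric(y), n1 = rnorm(n), n2 = rnorm(n),
             n3 = rnorm(n))
  w <- mi_weights(x, y)
  expect_gt(unname(w$weights[["copy"]]), 0.8)
  expect_equal(sum(w$weights), 1, tolerance = 1e-9)

  n <- 1000
  y <- rep(c(0L, 1L), each = n / 2)
  # independent features: estimates often clamp to zero, in which case the
  # uniform fallback (with its warning) is the documented behaviour
  wbar <- rowMeans(vapply(1:10, function(s) {
    set.seed(300 + s)
    suppressWarnings(
      unname(mi_weights(matrix(rnorm(n * 4), n, 4), y, seed = s)$weights))
  }, numeric(4)))
  expect_true(all(abs(wbar - 0.25) < 0.5 / 4))
})

test_that("fuse_weights sums components and refuses misaligned names", {
  nm <- c("a", "b")
  mk <- function(w, src) {
    v <- list(feature_names = nm, weights = stats::setNames(w, nm),
              source = src)
    class(v) <- "weight_vector"
    v
  }
  f <- fuse_weights(mk(c(1, 0), "rfe"), mk(c(0, 1), "extra_trees"),
                    mk(c(0.5, 0.5), "mutual_info"))
  expect_equal(unname(f$fused), c(1.5, 1.5))
  expect_equal(sum(f$fused), 3)

  u <- rep(1 / 4, 4)
  nm4 <- letters[1:4]
  mk4 <- function(src) {
    v <- list(feature_names = nm4, weights = stats::setNames(u, nm4),
              source = src)
    class(v) <- "weight_vector"
    v
  }
  f4 <- fuse_weights(mk4("rfe"), mk4("extra_trees"), mk4("mutual_info"))
  expect_equal(unname(f4$fused), rep(3 / 4, 4))

  bad <- mk(c(1, 0), "rfe")
  bad$feature_names <- c("b", "a")
  expect_error(fuse_weights(bad, mk(c(0, 1), "e"), mk(c(0.5, 0.5), "m")),
               "refusing to realign")
})

fused_from <- function(w) {
  nm <- names(w)
  third <- stats::setNames(rep(1 / length(w), length(w)), nm)
  structure(list(feature_names = nm, fused = w,
                 components = list(rfe = w / 3, extra_trees = w / 3,
                                   mutual_info = w / 3)),
            class = "fused_weights")
}

test_that("select_features drops floor(f*n) lightest with deterministic ties", {
  w52 <- stats::setNames(seq(1, 2, length.out = 52), names(feature_schema()))
  sel <- select_features(fused_from(w52), 0.20)
  expect_length(sel$retained, 42)
  expect_length(sel$dropped, 10)
  expect_setequal(c(sel$retained, sel$dropped), names(w52))

  w10 <- stats::setNames(10:1, paste0("f", 1:10))
  expect_length(select_features(fused_from(w10), 0.20)$retained, 8)

  # all-equal weights: the tie rule drops the last schema feature
  w5 <- stats::setNames(rep(1, 5), paste0("f", 1:5))
  sel5 <- select_features(fused_from(w5), 0.20)
  expect_identical(sel5$dropped, "f5")
  expect_identical(sel5$retained, paste0("f", 1:4))

  expect_error(select_features(fused_from(w5), 1), "drop_fraction")
})

test_that("select_features agrees with exhaustive sorting for n <= 6", {
  oracle <- function(w, frac) {
    n <- length(w)
    n_drop <- floor(frac * n)
    if (n_drop == 0) return(names(w))
    # exhaustive: enumerate all subsets of size n_drop and drop the unique
    # one with minimal total weight (weights drawn continuous, so no ties)
    combos <- utils::combn(n, n_drop)
    tot <- apply(combos, 2, function(ix) sum(w[ix]))
    stopifnot(sum(tot == min(tot)) == 1)
    names(w)[setdiff(seq_len(n), combos[, which.min(tot)])]
  }
  set.seed(17)
  for (i in 1:40) {
    n <- sample(2:6, 1)
    w <- stats::setNames(runif(n), paste0("f", 1:n))
    frac <- sample(c(0.2, 0.34, 0.5), 1)
    expect_identical(select_features(fused_from(w), frac)$retained,
                     oracle(w, frac))
  }
})

test_that("raising a feature's fused weight never demotes it", {
  set.seed(23)
  w <- stats::setNames(runif(12), paste0("f", 1:12))
  sel <- select_features(fused_from(w), 0.25)
  for (f in sel$retained) {
    w2 <- w
    w2[f] <- w2[f] + runif(1, 0.01, 2)
    expect_true(f %in% select_features(fused_from(w2), 0.25)$retained)
  }
})

test_that("fusion_select on a feature table returns the reduced table", {
  cfg <- scenario_config(n_depressed = 30, n_control = 60, effect_size = 2)
  tab <- generate_feature_table(cfg, seed = 11)
  out <- fusion_select(tab, seed = 2)
  expect_equal(ncol(out$table$x), 42)
  expect_identical(colnames(out$table$x), out$selection$retained)
  # retained order follows the original schema
  expect_identical(out$selection$retained,
                   intersect(colnames(tab$x), out$selection$retained))
})
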