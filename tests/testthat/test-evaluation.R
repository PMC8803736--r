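test_that("stratified_split keeps per-class proportions within one sample", {
  y <- c(rep(1L, 130), rep(0L, 320))
  sp <- stratified_split(y, 0.25, seed = 3)
  expect_setequal(c(sp$train, sp$test), seq_along(y))
  expect_length(intersect(sp$train, sp$test), 0)
  expect_true(sum(y[sp$test] == 1L) %in% c(32L, 33L))
  expect_equal(sum(y[sp$test] == 0L), 80L)
  expect_identical(stratified_split(y, 0.25, seed = 3), sp)
  expect_error(stratified_split(c(0L, 0L, 1L), 0.25), "at least 2")
})

test_that("compute_metrics matches a hand confusion matrix", {
  m <- compute_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0))
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 0.5)
  expect_equal(m$f1, 2 / 3)
  expect_equal(m$accuracy, 0.75)
  expect_equal(c(m$tp, m$fp, m$tn, m$fn), c(1, 0, 2, 1))

  perfect <- compute_metrics(c(1, 0, 1), c(1, 0, 1))
  expect_equal(c(perfect$accuracy, perfect$precision, perfect$recall,
                 perfect$f1), rep(1, 4))

  expect_warning(expect_warning(m0 <- compute_metrics(c(1, 1, 0), c(0, 0, 0)),
                                "precision"), "F1")
  expect_equal(m0$precision, 0)
  expect_error(compute_metrics(integer(), integer()), "empty")

  # flipping the positive class swaps the confusion roles
  m_flip <- compute_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0),
                            positive_class = 0L)
  expect_equal(m_flip$recall, 1)
  expect_equal(m_flip$precision, 2 / 3)
})

test_that("f1_from_pr is the 4-decimal harmonic mean", {
  expect_equal(f1_from_pr(0.8791, 1.0000), 0.9357)
  expect_equal(f1_from_pr(0.8242, 0.9375), 0.8772)
  for (x in c(0.3, 0.5, 0.9363)) expect_equal(f1_from_pr(x, x), round(x, 4))
  expect_equal(f1_from_pr(0.5, 0.25, report = FALSE), 1 / 3)
  expect_error(f1_from_pr(0, 0), "positive")
})

test_that("improvement_pp is absolute percentage points, 2 decimals", {
  expect_equal(improvement_pp(0.9313, 0.8496), 8.17)
  expect_equal(improvement_pp(0.9563, 0.9027), 5.36)
  expect_equal(improvement_pp(0.77, 0.77), 0)
  expect_equal(improvement_pp(0.8, 0.9), -10)
})

test_that("friedman_test matches the closed form and the base implementation", {
  # identical columns -> statistic 0
  s0 <- matrix(rep(c(0.7, 0.8, 0.6), 3), 3, 3)
  expect_equal(friedman_test(s0)$statistic, 0)

  # strictly consistent ordering over 4 units, 3 methods -> statistic 8
  sc <- matrix(c(0.1, 0.2, 0.3,
                 0.4, 0.5, 0.6,
                 0.2, 0.4, 0.9,
                 0.3, 0.5, 0.7), 4, 3, byrow = TRUE)
  out <- friedman_test(sc)
  expect_equal(out$statistic, 8)
  expect_equal(out$df, 2L)

  # tie-free random matrices agree with stats::friedman.test
  set.seed(41)
  for (i in 1:20) {
    n <- sample(2:5, 1); k <- sample(2:4, 1)
    m <- matrix(sample(seq_len(n * k)) / 10, n, k)
    ours <- friedman_test(m)
    base <- stats::friedman.test(m)
    expect_equal(ours$statistic, unname(base$statistic), tolerance = 1e-12)
    expect_equal(ours$p_value, unname(base$p.value), tolerance = 1e-12)
  }

  # column permutation leaves the statistic unchanged
  perm <- sample(3)
  expect_equal(friedman_test(sc[, perm])$statistic,
               friedman_test(sc)$statistic)
  expect_error(friedman_test(matrix(1:4, 4, 1)), "2 methods")
})

test_that("wilcoxon_pairwise: exact small-sample p-values and symmetry", {
  sc <- cbind(a = c(0.9, 0.8, 0.7, 0.85, 0.95, 0.75),
              b = c(0.8, 0.7, 0.6, 0.80, 0.90, 0.70))
  sc[, "b"] <- sc[, "a"] - c(0.1, 0.1, 0.1, 0.05, 0.05, 0.05)
  p <- suppressWarnings(wilcoxon_pairwise(sc))
  # one column uniformly greater, n = 6 -> exact two-sided p = 2/64
  expect_equal(p["a", "b"], 2 / 64)
  expect_equal(p, t(p))
  expect_equal(diag(p), c(a = 1, b = 1))

  # a column against itself -> all differences zero -> p = 1 with warning
  expect_warning(p_self <- wilcoxon_pairwise(cbind(x = sc[, 1],
                                                   y = sc[, 1])),
                 "all differences zero")
  expect_equal(p_self["x", "y"], 1)

  # tie-free data agrees with the base exact signed-rank test
  set.seed(52)
  for (i in 1:10) {
    a <- runif(8); b <- a + rnorm(8, 0, 0.2)
    ours <- suppressWarnings(wilcoxon_pairwise(cbind(a = a, b = b)))["a", "b"]
    base <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value
    expect_equal(ours, base, tolerance = 1e-12)
  }
})

test_that("run_experiment report has the full model x method x metric structure", {
  tab <- generate_feature_table(
    scenario_config(n_depressed = 24, n_control = 48, effect_size = 1.5),
    seed = 8)
  rep <- suppressWarnings(run_experiment(tab, seed = 2, cv_folds = 5,
                                         tune = FALSE))
  tm <- rep$test_metrics
  # 3 feature-set models x 6 methods x {unbalanced, balanced}
  expect_equal(nrow(tm), 36)
  expect_setequal(unique(tm$model), c("textual", "behavior", "both"))
  expect_equal(sum(!tm$balanced & tm$model == "both"), 6)
  # 72 test-metric cells per balance setting
  expect_equal(length(c(t(as.matrix(tm[!tm$balanced,
                                       c("accuracy", "precision", "recall",
                                         "f1")])))), 72)

  # every reported F1 is the harmonic mean of its own P/R cells
  pr <- tm$precision + tm$recall
  expect_equal(tm$f1[pr > 0],
               (2 * tm$precision * tm$recall / pr)[pr > 0],
               tolerance = 1e-12)
  # min(P,R) <= F1 <= max(P,R)
  expect_true(all(tm$f1 >= pmin(tm$precision, tm$recall) - 1e-12))
  expect_true(all(tm$f1 <= pmax(tm$precision, tm$recall) + 1e-12))

  # balanced-vs-unbalanced table: 6 improvement cells via improvement_pp
  expect_equal(nrow(rep$improvement), 6)
  expect_equal(rep$improvement$improve_pp,
               improvement_pp(rep$improvement$acc_balanced,
                              rep$improvement$acc_unbalanced))

  # paired CV matrix: complete, with the rank tests attached
  expect_equal(dim(rep$cv_scores$both), c(5L, 6L))
  expect_false(anyNA(rep$cv_scores$both))
  expect_named(rep$friedman, "both")
  expect_equal(dim(rep$wilcoxon$both), c(6L, 6L))
})
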