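test_that("pos_proportions matches hand counts and normalizes", {
  inv <- default_pos_inventory()
  tagged <- data.frame(token = rep("t", 10), pos = rep("n", 10))
  p <- pos_proportions(tagged, inv)
  expect_equal(unname(p[["n"]]), 1)
  expect_equal(sum(p), 1)

  tagged <- data.frame(token = letters[1:4], pos = c("n", "n", "v", "a"))
  p <- pos_proportions(tagged, inv)
  expect_equal(unname(p[c("n", "v", "a")]), c(0.5, 0.25, 0.25))
  expect_equal(sum(p), 1, tolerance = 1e-9)

  set.seed(7)
  for (i in 1:5) {
    tg <- data.frame(token = "x",
                     pos = sample(inv, sample(5:50, 1), replace = TRUE))
    expect_equal(sum(pos_proportions(tg, inv)), 1, tolerance = 1e-9)
  }

  expect_warning(p0 <- pos_proportions(data.frame(token = character(),
                                                  pos = character()), inv),
                 "no tokens")
  expect_true(all(p0 == 0))
})

test_that("lexicon_rates are per-1000-token membership rates", {
  lex <- lexicon_set(list(negation = "not", sad = "down"))
  tagged <- data.frame(token = c("i", "feel", "down"))
  r <- lexicon_rates(tagged, lex, c("sad", "negation"))
  expect_equal(unname(r[["sad"]]), 1 / 3 * 1000)
  expect_equal(unname(r[["negation"]]), 0)

  # duplicated matching token: 5 of 10 tokens in the lexicon -> rate 500
  lex2 <- lexicon_set(list(first_singular = "me"))
  tagged2 <- data.frame(token = c(rep("me", 5), paste0("w", 1:5)))
  expect_equal(unname(lexicon_rates(tagged2, lex2)[["first_singular"]]), 500)

  expect_error(lexicon_rates(tagged, lex, "missing_cat"), "unknown")
})

test_that("polarity proportions cover annotated posts only", {
  expect_equal(unname(polarity_proportions(c(0L, 0L, 1L, 2L))),
               c(0.5, 0.25, 0.25))
  expect_equal(unname(polarity_proportions(c(2L, 2L))), c(0, 0, 1))
  expect_equal(unname(polarity_proportions(c(0L, NA, 2L))), c(0.5, 0, 0.5))
  expect_warning(p <- polarity_proportions(c(NA_integer_, NA_integer_)),
                 "no polarity")
  expect_true(all(p == 0))
})

test_that("behavior features: habit proportions, half-open hour bins, ISO week", {
  # 2021-03-01 is a Monday
  b <- behavior_features(make_posts(rep("2021-03-01 02:00:00", 3)))
  expect_equal(unname(b[c("time_h00", "time_h06", "time_h12", "time_h18")]),
               c(1, 0, 0, 0))
  expect_equal(unname(b[["time_mon"]]), 1)
  expect_equal(unname(b[["time_sun"]]), 0)

  b2 <- behavior_features(make_posts(
    rep("2021-03-01 10:00:00", 4),
    is_original = c(TRUE, FALSE, FALSE, FALSE)))
  expect_equal(unname(b2[["habit_original"]]), 0.25)

  # boundary: 05:59 is in the first bin, 06:00 in the second
  b3 <- behavior_features(make_posts(c("2021-03-01 05:59:00",
                                       "2021-03-01 06:00:00")))
  expect_equal(unname(b3[c("time_h00", "time_h06", "time_h12", "time_h18")]),
               c(0.5, 0.5, 0, 0))
  expect_equal(sum(b3[grep("^time_h", names(b3))]), 1)
  expect_equal(sum(b3[grep("^time_(mon|tue|wed|thu|fri|sat|sun)",
                           names(b3))]), 1)
})

test_that("build_feature_table assembles the 52-feature schema per group", {
  users <- list(
    make_user("u1", c("2021-03-01 02:00:00", "2021-03-02 13:00:00"),
              text = c("i feel down", "not why joy"),
              polarity = c(0L, 1L), label = 1L),
    make_user("u2", "2021-03-06 19:30:00", text = "we fond whoa",
              polarity = 2L, label = 0L),
    make_user("u3", "2021-03-07 07:00:00", text = "he rage yuck",
              label = 0L)
  )
  lex <- toy_lexicons()
  tagger <- fallback_tagger(c(i = "r", we = "r", he = "r", down = "a",
                              joy = "a", not = "d", why = "y"))
  tab <- suppressWarnings(build_feature_table(users, lex, tagger))
  expect_equal(dim(tab), c(3L, 52L))
  expect_identical(colnames(tab$x), names(feature_schema()))
  expect_equal(sum(tab$groups == "textual"), 38)
  expect_equal(sum(tab$groups == "behavior"), 14)

  # hand-checked cells for u1: 6 tokens, "down" in sad, "not" in negation
  expect_equal(unname(tab$x["u1", "emo_sad"]), 1 / 6 * 1000)
  expect_equal(unname(tab$x["u1", "sw_negation"]), 1 / 6 * 1000)
  expect_equal(unname(tab$x["u1", "pron_first_singular"]), 1 / 6 * 1000)
  expect_equal(unname(tab$x["u1", "pos_r"]), 1 / 6)
  expect_equal(unname(tab$x["u1", "pol_negative"]), 0.5)
  expect_equal(unname(tab$x["u1", "time_h00"]), 0.5)

  tb_text <- suppressWarnings(build_feature_table(users, lex, tagger,
                                                  schema = "textual"))
  expect_equal(ncol(tb_text$x), 38)
  tb_beh <- suppressWarnings(build_feature_table(users, lex, tagger,
                                                 schema = "behavior"))
  expect_equal(ncol(tb_beh$x), 14)
})

test_that("features are invariant to duplicating a user's posts k times", {
  lex <- toy_lexicons()
  tagger <- fallback_tagger(c(i = "r", down = "a"))
  posts <- make_posts(c("2021-03-01 02:00:00", "2021-03-03 15:00:00"),
                      text = c("i feel down", "not much here"),
                      is_original = c(TRUE, FALSE),
                      has_picture = c(TRUE, FALSE),
                      polarity = c(0L, 2L))
  u1 <- user_record("u", posts, label = 1L)
  u3 <- user_record("u", posts[rep(1:2, 3), ], label = 1L)
  t1 <- suppressWarnings(build_feature_table(list(u1), lex, tagger))
  t3 <- suppressWarnings(build_feature_table(list(u3), lex, tagger))
  expect_equal(t1$x, t3$x, tolerance = 1e-12)
})

test_that("featurization is deterministic given tagger, lexicons and input", {
  corp <- generate_corpus(scenario_config(n_depressed = 5, n_control = 10),
                          seed = 3)
  tagger <- fallback_tagger(corp$tag_map)
  t1 <- build_feature_table(corp$users, corp$lexicons, tagger)
  t2 <- build_feature_table(corp$users, corp$lexicons, tagger)
  expect_identical(t1$x, t2$x)
})
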