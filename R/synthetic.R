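#' Synthetic corpora and feature tables
#'
#' The study population this generator emulates is a microblog community with
#' a depressed minority (130 users) and a control majority (320 users).
#' Depressed users are given the signal structure reported for such cohorts:
#' elevated rates of negation words, first-person-singular pronouns and sad
#' emotion words, a late-night (00:00-06:00) posting peak, fewer picture
#' posts, and more negative post polarity. Two generation paths are
#' provided: a corpus-level path that emits post streams (exercising the
#' tagger and featurizer end to end) and a table-level path that plants
#' exact standardized mean shifts on chosen features (giving precise control
#' of effect sizes for selector/classifier benchmarks).
#'
#' @name synthetic_data
NULL

#' Scenario configuration
#'
#' @param n_depressed,n_control Class sizes (defaults 130 and 320, the
#'   reference cohort's imbalance).
#' @param separation Scales every class difference of the corpus path; 0
#'   gives an exact null scenario (classes exchangeable).
#' @param posts_meanlog,posts_sdlog Log-normal posts-per-user distribution
#'   (default median ~20 posts).
#' @param tokens_lambda Poisson mean of tokens per post (plus one).
#' @param planted_features,effect_size Table path: features receiving a
#'   standardized class mean-shift and its size (default five informative
#'   features at d = 1.5).
#' @param noise_sd Table path: standard deviation of the exchangeable noise.
#' @param seed Default seed used when a generator call does not override it.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(n_depressed = 130L, n_control = 320L,
                            separation = 1,
                            posts_meanlog = 3, posts_sdlog = 0.5,
                            tokens_lambda = 8,
                            planted_features = c("sw_negation",
                                                 "pron_first_singular",
                                                 "emo_sad", "time_h00",
                                                 "habit_picture"),
                            effect_size = 1.5,
                            noise_sd = 1,
                            seed = 1L) {
  stopifnot(n_depressed >= 2L, n_control >= 2L, separation >= 0,
            effect_size >= 0, noise_sd > 0, tokens_lambda > 0)
  structure(
    list(n_depressed = as.integer(n_depressed),
         n_control = as.integer(n_control),
         separation = separation,
         posts_meanlog = posts_meanlog, posts_sdlog = posts_sdlog,
         tokens_lambda = tokens_lambda,
         planted_features = planted_features, effect_size = effect_size,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "scenario_config"
  )
}

#' Built-in synthetic lexicons and tag map
#'
#' Synthetic ASCII token vocabularies for every lexicon category the
#' featurizer scores (seven emotions, six pronoun classes, negation,
#' interrogative) plus filler tokens, and a token -> POS tag map for the
#' fallback tagger. Tokens are placeholders sufficient to exercise the
#' counting logic, not natural language.
#'
#' @return List with elements `lexicons` (a [lexicon_set()]) and `tag_map`
#'   (named character vector).
#' @export
builtin_lexicons <- function() {
  mk <- function(prefix, n) sprintf("%s%02d", prefix, seq_len(n))
  cats <- c(
    stats::setNames(lapply(EMOTION_CATS, function(cat) mk(cat, 8L)),
                    EMOTION_CATS),
    stats::setNames(lapply(PRONOUN_CATS, function(cat) mk(cat, 4L)),
                    PRONOUN_CATS),
    stats::setNames(lapply(SPECIFIC_CATS, function(cat) mk(cat, 6L)),
                    SPECIFIC_CATS)
  )
  lex <- lexicon_set(cats)
  filler <- mk("filler", 40L)
  # tag assignments: pronouns are tagged r, negations d, interrogatives y,
  # emotion words spread over open classes, filler cycles the inventory
  inv <- default_pos_inventory()
  tag_map <- c(
    stats::setNames(rep("r", sum(lengths(cats[PRONOUN_CATS]))),
                    unlist(cats[PRONOUN_CATS])),
    stats::setNames(rep("d", length(cats$negation)), cats$negation),
    stats::setNames(rep("y", length(cats$interrogative)), cats$interrogative),
    stats::setNames(rep(c("a", "v", "n", "i", "o", "z", "e"),
                        times = lengths(cats[EMOTION_CATS])),
                    unlist(cats[EMOTION_CATS])),
    stats::setNames(inv[(seq_along(filler) - 1L) %% length(inv) + 1L],
                    filler)
  )
  list(lexicons = lex, tag_map = tag_map, filler = filler)
}

# class-conditional generation parameters; all contrasts scale with
# cfg$separation (0 = null scenario)
class_profiles <- function(cfg) {
  s <- cfg$separation
  base_mix <- c(happy = 0.04, like = 0.04, anger = 0.02, sad = 0.03,
                fear = 0.02, surprise = 0.02, disgust = 0.02,
                first_singular = 0.05, first_plural = 0.02,
                second_singular = 0.02, second_plural = 0.01,
                third_person = 0.03, others_word = 0.02,
                negation = 0.03, interrogative = 0.02, filler = 0.63)
  # Contrasts are mild at the post level because per-user aggregation over
  # dozens of posts shrinks within-class variance: strong post-level shifts
  # would make the user classes implausibly separable.
  dep_shift <- c(happy = -0.006, like = -0.006, anger = 0.003, sad = 0.015,
                 fear = 0.003, surprise = 0, disgust = 0.003,
                 first_singular = 0.018, first_plural = -0.003,
                 second_singular = 0, second_plural = 0,
                 third_person = -0.003, others_word = 0.006,
                 negation = 0.018, interrogative = 0.003, filler = -0.051)
  dep_mix <- base_mix + s * dep_shift
  dep_mix <- pmax(dep_mix, 0.001); dep_mix <- dep_mix / sum(dep_mix)

  base_hour <- c(0.10, 0.25, 0.30, 0.35)       # 6-hour bins, daytime-heavy
  dep_hour <- base_hour + s * c(0.08, -0.03, -0.03, -0.02)
  dep_hour <- pmax(dep_hour, 0.01); dep_hour <- dep_hour / sum(dep_hour)

  clamp01 <- function(p) pmin(pmax(p, 0.02), 0.98)
  list(
    control = list(mix = base_mix, hour = base_hour,
                   habits = c(original = 0.60, picture = 0.50,
                              location = 0.30),
                   polarity = c(0.20, 0.40, 0.40)),
    depressed = list(mix = dep_mix, hour = dep_hour,
                     habits = clamp01(c(original = 0.60, picture = 0.50,
                                        location = 0.30) +
                                        s * c(0.06, -0.10, -0.06)),
                     polarity = {
                       p <- c(0.20, 0.40, 0.40) + s * c(0.15, -0.04, -0.11)
                       p <- pmax(p, 0.02); p / sum(p)
                     })
  )
}

#' Generate a synthetic labelled corpus
#'
#' Draws users of both classes, each with a log-normal number of posts;
#' post tokens come from class-dependent mixtures over the built-in
#' lexicons, timestamps from class-dependent 6-hour-bin distributions
#' (weekday uniform), behavior flags from class Bernoulli rates and polarity
#' from a class categorical. Deterministic per seed.
#'
#' @param cfg A [scenario_config()].
#' @param seed Overrides `cfg$seed` when given.
#' @return List with `users` (list of [user_record()]), `lexicons`,
#'   `tag_map`.
#' @export
generate_corpus <- function(cfg = scenario_config(), seed = cfg$seed) {
  stopifnot(inherits(cfg, "scenario_config"))
  built <- builtin_lexicons()
  prof <- class_profiles(cfg)
  vocab <- c(lapply(built$lexicons, identity), list(filler = built$filler))

  n <- cfg$n_depressed + cfg$n_control
  labels <- c(rep(1L, cfg$n_depressed), rep(0L, cfg$n_control))
  users <- with_seed(seed, {
    labels <- sample(labels)  # interleave classes
    lapply(seq_len(n), function(i) {
      cl <- if (labels[i] == 1L) prof$depressed else prof$control
      n_posts <- max(3L, as.integer(round(stats::rlnorm(
        1, cfg$posts_meanlog, cfg$posts_sdlog))))
      hours_bin <- sample.int(4L, n_posts, replace = TRUE, prob = cl$hour)
      hour <- (hours_bin - 1L) * 6L + sample.int(6L, n_posts,
                                                 replace = TRUE) - 1L
      day <- sample.int(364L, n_posts, replace = TRUE)
      ts <- as.POSIXct("2021-01-04", tz = "UTC") +
        (day - 1L) * 86400 + hour * 3600 +
        sample.int(60L, n_posts, replace = TRUE) * 60
      texts <- vapply(seq_len(n_posts), function(p) {
        n_tok <- stats::rpois(1, cfg$tokens_lambda) + 1L
        cat_draw <- sample(names(cl$mix), n_tok, replace = TRUE,
                           prob = cl$mix)
        toks <- vapply(cat_draw, function(catg) {
          sample(vocab[[catg]], 1L)
        }, "")
        paste(toks, collapse = " ")
      }, "")
      posts <- data.frame(
        text = texts, timestamp = ts,
        is_original = stats::runif(n_posts) < cl$habits[["original"]],
        has_picture = stats::runif(n_posts) < cl$habits[["picture"]],
        has_location = stats::runif(n_posts) < cl$habits[["location"]],
        polarity = sample(VALID_POLARITY, n_posts, replace = TRUE,
                          prob = cl$polarity),
        stringsAsFactors = FALSE
      )
      user_record(sprintf("user_%04d", i), posts, label = labels[i])
    })
  })
  list(users = users, lexicons = built$lexicons, tag_map = built$tag_map)
}

#' Generate a feature table with planted informative features
#'
#' Direct tabular generation over the default 52-feature schema: every
#' feature is Gaussian noise except the planted ones, whose depressed-class
#' mean is shifted by `effect_size` standard deviations. This path gives
#' exact control of the signal for feature-selection and classifier
#' benchmarks.
#'
#' @param cfg A [scenario_config()].
#' @param seed Overrides `cfg$seed` when given.
#' @return A labelled [feature_table()] with
#'   `n_depressed + n_control` rows.
#' @export
generate_feature_table <- function(cfg = scenario_config(), seed = cfg$seed) {
  stopifnot(inherits(cfg, "scenario_config"))
  groups <- feature_schema()
  schema <- names(groups)
  bad <- setdiff(cfg$planted_features, schema)
  if (length(bad)) {
    stop("planted features not in schema: ", paste(bad, collapse = ", "))
  }
  n <- cfg$n_depressed + cfg$n_control
  with_seed(seed, {
    labels <- sample(c(rep(1L, cfg$n_depressed), rep(0L, cfg$n_control)))
    x <- matrix(stats::rnorm(n * length(schema), sd = cfg$noise_sd),
                n, length(schema), dimnames = list(NULL, schema))
    for (f in cfg$planted_features) {
      x[labels == 1L, f] <- x[labels == 1L, f] +
        cfg$effect_size * cfg$noise_sd
    }
    feature_table(x, labels = labels,
                  user_ids = sprintf("user_%04d", seq_len(n)),
                  groups = groups)
  })
}
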