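# Small builders shared across tests. Everything is generated in code; no
# stored fixtures.

make_posts <- function(times,
                       text = rep("hello world", length(times)),
                       is_original = rep(TRUE, length(times)),
                       has_picture = rep(FALSE, length(times)),
                       has_location = rep(FALSE, length(times)),
                       polarity = rep(NA_integer_, length(times))) {
  data.frame(
    text = text,
    timestamp = as.POSIXct(times, tz = "UTC"),
    is_original = is_original,
    has_picture = has_picture,
    has_location = has_location,
    polarity = polarity,
    stringsAsFactors = FALSE
  )
}

make_user <- function(id = "u1", times = "2021-03-01 10:00:00", ...,
                      label = NA_integer_) {
  user_record(id, make_posts(times, ...), label = label)
}

toy_lexicons <- function() {
  lexicon_set(list(
    happy = c("joy", "yay"), like = c("fond"), anger = c("rage"),
    sad = c("blue", "down"), fear = c("afraid"), surprise = c("whoa"),
    disgust = c("yuck"),
    first_singular = c("i", "me"), first_plural = c("we", "us"),
    second_singular = c("thou"), second_plural = c("youse"),
    third_person = c("he", "she"), others_word = c("others"),
    negation = c("not", "never"), interrogative = c("why", "how")
  ))
}

# a linearly separable two-feature binary problem
separable_xy <- function(n_per_class = 20, gap = 4, seed = 42) {
  set.seed(seed)
  x <- rbind(
    cbind(rnorm(n_per_class), rnorm(n_per_class)),
    cbind(rnorm(n_per_class) + gap, rnorm(n_per_class) + gap)
  )
  colnames(x) <- c("f1", "f2")
  list(x = x, y = rep(c(0L, 1L), each = n_per_class))
}

# constant-probability custom base learner
constant_learner <- function(p) {
  learner_spec("custom", list(
    fit = function(x, y) p,
    predict_prob = function(model, x) rep(model, nrow(x))
  ))
}

# published benchmark report cells reproduced by the framework's arithmetic
# (per-model precision/recall/F1/accuracy of the six methods, and
# unbalanced/balanced accuracies); used to validate the report helpers.
reference_tables <- function() {
  methods <- c("svm", "nb", "knn", "lr_l1", "lr_l2", "stacking")
  ref_metrics <- rbind(
    data.frame(model = 1, method = methods,
               precision = c(0.7339, 0.8068, 0.8750, 0.8444, 0.8462, 0.8750),
               recall = c(0.9999, 0.8875, 0.9625, 0.9500, 0.9625, 0.9625),
               f1 = c(0.8465, 0.8452, 0.9166, 0.8941, 0.9006, 0.9166),
               accuracy = c(0.7434, 0.7699, 0.8761, 0.8407, 0.8496, 0.8761)),
    data.frame(model = 2, method = methods,
               precision = c(0.7080, 0.8434, 0.8256, 0.8202, 0.8242, 0.8256),
               recall = c(1.0000, 0.8750, 0.8875, 0.9125, 0.9375, 0.8875),
               f1 = c(0.8290, 0.8589, 0.8554, 0.8639, 0.8772, 0.8554),
               accuracy = c(0.7080, 0.7965, 0.7876, 0.7965, 0.8141, 0.7876)),
    data.frame(model = 3, method = methods,
               precision = c(0.8478, 0.8142, 0.8750, 0.8539, 0.8556, 0.8791),
               recall = c(0.9750, 0.9000, 0.9625, 0.9500, 0.9625, 1.0000),
               f1 = c(0.9070, 0.8727, 0.9166, 0.8994, 0.9059, 0.9357),
               accuracy = c(0.8584, 0.8142, 0.8761, 0.8496, 0.8584, 0.9027))
  )
  ref_balance <- data.frame(
    method = methods,
    unbalanced = c(0.8584, 0.8142, 0.8761, 0.8496, 0.8584, 0.9027),
    balanced = c(0.8688, 0.8875, 0.8938, 0.9313, 0.8750, 0.9563),
    improve = c(1.04, 7.33, 1.77, 8.17, 1.66, 5.36)
  )
  list(metrics = ref_metrics, balance = ref_balance)
}
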