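#' Per-user feature extraction
#'
#' Turns a user's post stream into one numeric feature vector. All features
#' are proportions or per-1000-token rates, never raw counts, so users with
#' very different posting volumes are comparable: duplicating every post of a
#' user k times leaves the whole vector unchanged.
#'
#' The default schema has 52 features in 7 blocks:
#' \itemize{
#'   \item `pos_*` (20): proportion of each part-of-speech tag over all the
#'     user's tokens;
#'   \item `emo_*` (7): per-1000-token rates of the seven emotion lexicons
#'     (happy, like, anger, sad, fear, surprise, disgust);
#'   \item `pron_*` (6): rates of pronoun classes (first singular/plural,
#'     second singular/plural, third person, "others");
#'   \item `sw_*` (2): rates of negation and interrogative words;
#'   \item `pol_*` (3): proportions of negative/neutral/positive posts among
#'     polarity-annotated posts;
#'   \item `habit_*` (3): fraction of original posts, posts with pictures,
#'     posts with location;
#'   \item `time_*` (11): fraction of posts in each 6-hour bin (half-open
#'     \code{[0,6) [6,12) [12,18) [18,24)}) and on each ISO weekday
#'     (Monday first).
#' }
#' The `pos_`/`emo_`/`pron_`/`sw_`/`pol_` blocks form the `"textual"` group
#' (38 features); `habit_`/`time_` form the `"behavior"` group (14).
#'
#' @name featurizer
NULL

#' Default part-of-speech tag inventory (20 tags)
#'
#' A jieba/ICTCLAS-style inventory covering the tags common in Chinese
#' microblog text, including Chinese-specific classes such as onomatopoeia
#' (`o`), idioms (`i`) and interjections (`e`). The inventory is a
#' convention: any 20-tag (or other sized) inventory can be passed to the
#' featurizer instead.
#'
#' @return Character vector of 20 tag codes.
#' @export
default_pos_inventory <- function() {
  c("n",  # noun
    "v",  # verb
    "a",  # adjective
    "d",  # adverb
    "r",  # pronoun
    "m",  # numeral
    "q",  # measure word
    "p",  # preposition
    "c",  # conjunction
    "u",  # particle
    "e",  # interjection
    "y",  # modal particle
    "o",  # onomatopoeia
    "i",  # idiom / set phrase
    "l",  # temporary lexeme
    "t",  # time word
    "f",  # locative
    "s",  # place word
    "z",  # status word
    "x")  # other / unknown
}

#' Whitespace + tag-map fallback tagger
#'
#' Real deployments plug in a Chinese segmenter/POS tagger; for synthetic
#' corpora and tests this fallback splits on whitespace and looks each token
#' up in a token -> tag map, assigning `default_tag` to unknown tokens. The
#' returned function is deterministic and total: every post maps to a
#' (possibly empty) data.frame of `token`, `pos`.
#'
#' @param tag_map Named character vector mapping tokens to POS tags.
#' @param default_tag Tag for tokens absent from the map.
#' @return A function `(text) -> data.frame(token, pos)`.
#' @export
fallback_tagger <- function(tag_map = character(), default_tag = "x") {
  force(tag_map); force(default_tag)
  function(text) {
    toks <- strsplit(trimws(text), "\\s+")[[1]]
    toks <- toks[nzchar(toks)]
    if (!length(toks)) {
      return(data.frame(token = character(), pos = character()))
    }
    pos <- unname(tag_map[toks])
    pos[is.na(pos)] <- default_tag
    data.frame(token = toks, pos = pos, stringsAsFactors = FALSE)
  }
}

#' Part-of-speech proportions over a user's tokens
#'
#' @param tagged data.frame with columns `token`, `pos` (all posts pooled).
#' @param inventory Tag inventory defining output order.
#' @return Named numeric vector over `inventory`; sums to 1 when at least one
#'   token is present, all zeros (with a warning) otherwise.
#' @export
pos_proportions <- function(tagged, inventory = default_pos_inventory()) {
  out <- stats::setNames(numeric(length(inventory)), inventory)
  n <- nrow(tagged)
  if (!n) {
    warning("user has no tokens; POS proportions set to 0")
    return(out)
  }
  tab <- table(factor(tagged$pos[tagged$pos %in% inventory],
                      levels = inventory))
  out[] <- as.numeric(tab) / n
  out
}

#' Lexicon match rates per 1000 tokens
#'
#' For each requested category, counts tokens that are members of the
#' category's term set and reports `matches / total_tokens * 1000`. The
#' per-1000 scaling removes post-volume effects while keeping typical rates
#' on an interpretable scale.
#'
#' @param tagged data.frame with column `token` (all of a user's posts pooled).
#' @param lexicons A [lexicon_set()].
#' @param categories Category names to score (must exist in `lexicons`).
#' @return Named numeric vector of per-1000-token rates.
#' @export
lexicon_rates <- function(tagged, lexicons, categories = names(lexicons)) {
  missing_c <- setdiff(categories, names(lexicons))
  if (length(missing_c)) {
    stop("unknown lexicon categories: ", paste(missing_c, collapse = ", "))
  }
  out <- stats::setNames(numeric(length(categories)), categories)
  n <- nrow(tagged)
  if (!n) {
    warning("user has no tokens; lexicon rates set to 0")
    return(out)
  }
  for (cat in categories) {
    out[[cat]] <- sum(tagged$token %in% lexicons[[cat]]) / n * 1000
  }
  out
}

#' Post polarity proportions
#'
#' Proportion of negative / neutral / positive posts among the posts that
#' carry a polarity annotation; posts with missing polarity are excluded from
#' the denominator rather than imputed.
#'
#' @param polarity Integer vector of per-post polarities (0/1/2 or `NA`).
#' @return Named 3-vector `(pol_negative, pol_neutral, pol_positive)` summing
#'   to 1, or all zeros (with a warning) when no post is annotated.
#' @export
polarity_proportions <- function(polarity) {
  out <- c(pol_negative = 0, pol_neutral = 0, pol_positive = 0)
  pol <- polarity[!is.na(polarity)]
  if (!length(pol)) {
    warning("no polarity-annotated posts; polarity proportions set to 0")
    return(out)
  }
  tab <- table(factor(pol, levels = VALID_POLARITY))
  out[] <- as.numeric(tab) / length(pol)
  out
}

#' Posting-behavior features
#'
#' Habit proportions (original / picture / location flags over all posts) and
#' posting-rhythm distributions: fraction of posts in each of four half-open
#' 6-hour bins and on each ISO weekday (Monday first). Posts whose timestamp
#' cannot be used are excluded from the rhythm features (with a warning) but
#' still count toward the habit proportions.
#'
#' @param posts A post data.frame as in [user_record()].
#' @return Named 14-vector: `habit_original`, `habit_picture`,
#'   `habit_location`, `time_h00/h06/h12/h18`, `time_mon`..`time_sun`.
#' @export
behavior_features <- function(posts) {
  n <- nrow(posts)
  stopifnot(n >= 1)
  habits <- c(habit_original = mean(posts$is_original),
              habit_picture = mean(posts$has_picture),
              habit_location = mean(posts$has_location))

  ok <- !is.na(posts$timestamp)
  if (!all(ok)) warning(sum(!ok), " post(s) with unusable timestamps excluded from time features")
  hours <- as.integer(format(posts$timestamp[ok], "%H"))
  wday <- as.integer(format(posts$timestamp[ok], "%u"))  # 1 = Monday
  m <- sum(ok)
  hour_bins <- stats::setNames(numeric(4), c("time_h00", "time_h06",
                                             "time_h12", "time_h18"))
  week <- stats::setNames(numeric(7), paste0(
    "time_", c("mon", "tue", "wed", "thu", "fri", "sat", "sun")))
  if (m > 0) {
    hour_bins[] <- as.numeric(table(factor(hours %/% 6L, levels = 0:3))) / m
    week[] <- as.numeric(table(factor(wday, levels = 1:7))) / m
  }
  c(habits, hour_bins, week)
}

# canonical lexicon category -> feature-name blocks
EMOTION_CATS <- c("happy", "like", "anger", "sad", "fear", "surprise",
                  "disgust")
PRONOUN_CATS <- c("first_singular", "first_plural", "second_singular",
                  "second_plural", "third_person", "others_word")
SPECIFIC_CATS <- c("negation", "interrogative")

#' Names and groups of the default feature schema
#'
#' @param inventory POS tag inventory.
#' @param schema Feature groups to include: `"textual"`, `"behavior"` or both.
#' @return Named character vector mapping feature names to groups.
#' @export
feature_schema <- function(inventory = default_pos_inventory(),
                           schema = c("textual", "behavior")) {
  schema <- match.arg(schema, several.ok = TRUE)
  textual <- c(paste0("pos_", inventory),
               paste0("emo_", EMOTION_CATS),
               paste0("pron_", PRONOUN_CATS),
               paste0("sw_", SPECIFIC_CATS),
               c("pol_negative", "pol_neutral", "pol_positive"))
  behavior <- c("habit_original", "habit_picture", "habit_location",
                "time_h00", "time_h06", "time_h12", "time_h18",
                paste0("time_", c("mon", "tue", "wed", "thu", "fri", "sat",
                                  "sun")))
  out <- c(stats::setNames(rep("textual", length(textual)), textual),
           stats::setNames(rep("behavior", length(behavior)), behavior))
  out[out %in% schema]
}

#' Build a per-user feature table from user records
#'
#' Runs the tagger over every post, pools tokens per user and assembles the
#' full feature schema (see [featurizer]). Users failing every precondition
#' (e.g. zero tokens) get a row of zeros in the affected blocks and are
#' reported as exclusion candidates.
#'
#' @param users List of [user_record()] objects.
#' @param lexicons A [lexicon_set()] containing at least the emotion, pronoun
#'   and specific-word categories.
#' @param tagger A tagger function (see [fallback_tagger()]).
#' @param inventory POS tag inventory.
#' @param schema `"textual"`, `"behavior"` or both (default): which feature
#'   groups to compute.
#' @return A [feature_table()] with one row per user, in input order.
#' @export
build_feature_table <- function(users, lexicons,
                                tagger = fallback_tagger(),
                                inventory = default_pos_inventory(),
                                schema = c("textual", "behavior")) {
  schema <- match.arg(schema, several.ok = TRUE)
  groups <- feature_schema(inventory, schema)
  lex_cats <- c(EMOTION_CATS, PRONOUN_CATS, SPECIFIC_CATS)
  if ("textual" %in% schema) {
    missing_c <- setdiff(lex_cats, names(lexicons))
    if (length(missing_c)) {
      stop("lexicon set lacks categories: ", paste(missing_c, collapse = ", "))
    }
  }
  rows <- lapply(users, function(u) {
    p <- u$posts
    vec <- numeric(0)
    if ("textual" %in% schema) {
      tagged <- do.call(rbind, lapply(p$text, tagger))
      if (is.null(tagged)) tagged <- data.frame(token = character(),
                                                pos = character())
      if (!nrow(tagged)) {
        dep_log("user ", u$user_id, " has no tokens; exclusion candidate",
                level = "WARN")
      }
      pos <- withCallingHandlers(
        pos_proportions(tagged, inventory),
        warning = function(w) invokeRestart("muffleWarning"))
      lex <- withCallingHandlers(
        lexicon_rates(tagged, lexicons, lex_cats),
        warning = function(w) invokeRestart("muffleWarning"))
      pol <- withCallingHandlers(
        polarity_proportions(p$polarity),
        warning = function(w) invokeRestart("muffleWarning"))
      names(pos) <- paste0("pos_", names(pos))
      names(lex) <- c(paste0("emo_", EMOTION_CATS),
                      paste0("pron_", PRONOUN_CATS),
                      paste0("sw_", SPECIFIC_CATS))
      vec <- c(vec, pos, lex, pol)
    }
    if ("behavior" %in% schema) {
      vec <- c(vec, withCallingHandlers(
        behavior_features(p),
        warning = function(w) invokeRestart("muffleWarning")))
    }
    vec[names(groups)]
  })
  x <- do.call(rbind, rows)
  colnames(x) <- names(groups)
  feature_table(x,
                labels = vapply(users, `[[`, 0L, "label"),
                user_ids = vapply(users, `[[`, "", "user_id"),
                groups = groups)
}
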