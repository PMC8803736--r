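#' User post streams, lexicon sets and feature tables
#'
#' The pipeline's interchange objects. A *user record* holds one labelled (or
#' unlabelled) user and their ordered post stream; a *lexicon set* maps
#' category names (seven emotions, pronoun classes, negation, interrogative
#' words, ...) to term sets; a *feature table* holds one named numeric feature
#' vector per user plus binary labels and is what every downstream stage
#' consumes.
#'
#' @name corpus_io
NULL

VALID_POLARITY <- c(0L, 1L, 2L)

#' Construct a user record
#'
#' @param user_id Character scalar identifying the user.
#' @param posts A data.frame with columns `text`, `timestamp` (POSIXct),
#'   `is_original`, `has_picture`, `has_location` (logical) and `polarity`
#'   (integer 0 = negative, 1 = neutral, 2 = positive, or `NA`).
#' @param label 1 (depressed), 0 (control) or `NA` for unlabelled users.
#' @return An object of class `user_record`.
#' @export
user_record <- function(user_id, posts, label = NA_integer_) {
  stopifnot(is.character(user_id), length(user_id) == 1L, is.data.frame(posts))
  needed <- c("text", "timestamp", "is_original", "has_picture",
              "has_location", "polarity")
  missing_cols <- setdiff(needed, names(posts))
  if (length(missing_cols)) {
    stop("posts is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  pol <- posts$polarity
  if (any(!is.na(pol) & !pol %in% VALID_POLARITY)) {
    stop("polarity values must be 0, 1, 2 or missing")
  }
  if (!is.na(label) && !label %in% c(0L, 1L)) stop("label must be 0, 1 or NA")
  posts <- posts[order(posts$timestamp), , drop = FALSE]
  rownames(posts) <- NULL
  structure(
    list(user_id = user_id, label = as.integer(label), posts = posts),
    class = "user_record"
  )
}

#' @export
print.user_record <- function(x, ...) {
  cat(sprintf("<user_record %s: %d posts, label=%s>\n",
              x$user_id, nrow(x$posts),
              ifelse(is.na(x$label), "?", x$label)))
  invisible(x)
}

#' Read a JSON Lines post stream into user records
#'
#' One JSON object per line with fields `user_id`, `text`, `timestamp`
#' (`"YYYY-MM-DD HH:MM[:SS]"`), `is_original`, `has_picture`, `has_location`
#' and optional `polarity` (0/1/2). Posts are grouped by `user_id` and sorted
#' by timestamp; duplicated lines are preserved because per-user counts feed
#' the rate features. Labels may be attached from a sidecar CSV with columns
#' `user_id,label`, so unlabelled corpora can still be scored.
#'
#' @param path Path to the JSONL file.
#' @param labels_path Optional path to the sidecar labels CSV.
#' @return A list of [user_record()] objects, in order of first appearance.
#' @export
read_posts <- function(path, labels_path = NULL) {
  if (!file.exists(path)) stop("posts file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(list())

  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                    error = function(e) stop(sprintf(
                      "malformed JSON on line %d: %s", i, conditionMessage(e)),
                      call. = FALSE))
    if (is.null(obj$user_id) || is.null(obj$text) || is.null(obj$timestamp)) {
      stop(sprintf("line %d: user_id, text and timestamp are required", i))
    }
    pol <- obj$polarity
    if (!is.null(pol) && !is.na(pol) && !pol %in% VALID_POLARITY) {
      stop(sprintf("line %d: unknown polarity value %s", i, pol))
    }
    ts <- as.POSIXct(obj$timestamp, tz = "UTC",
                     tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                                    "%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d"))
    recs[[i]] <- data.frame(
      user_id = as.character(obj$user_id),
      text = as.character(obj$text),
      timestamp = ts,
      is_original = isTRUE(obj$is_original),
      has_picture = isTRUE(obj$has_picture),
      has_location = isTRUE(obj$has_location),
      polarity = if (is.null(pol) || is.na(pol)) NA_integer_ else as.integer(pol),
      stringsAsFactors = FALSE
    )
  }
  posts <- do.call(rbind, recs)

  labels <- NULL
  if (!is.null(labels_path)) {
    lab <- utils::read.csv(labels_path, stringsAsFactors = FALSE)
    if (!all(c("user_id", "label") %in% names(lab))) {
      stop("labels CSV must have columns user_id,label")
    }
    labels <- stats::setNames(as.integer(lab$label), as.character(lab$user_id))
  }

  ids <- unique(posts$user_id)
  lapply(ids, function(id) {
    u <- posts[posts$user_id == id, setdiff(names(posts), "user_id"),
               drop = FALSE]
    user_record(id, u,
                label = if (!is.null(labels) && id %in% names(labels))
                  labels[[id]] else NA_integer_)
  })
}

#' Write user records to a JSON Lines file (plus optional labels sidecar)
#'
#' @param users List of [user_record()] objects.
#' @param path Output JSONL path.
#' @param labels_path Optional path for the `user_id,label` sidecar CSV;
#'   written only for users with non-missing labels.
#' @return `path`, invisibly.
#' @export
write_posts <- function(users, path, labels_path = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (u in users) {
    p <- u$posts
    for (i in seq_len(nrow(p))) {
      rec <- list(
        user_id = u$user_id,
        text = p$text[i],
        timestamp = format(p$timestamp[i], "%Y-%m-%d %H:%M:%S", tz = "UTC"),
        is_original = p$is_original[i],
        has_picture = p$has_picture[i],
        has_location = p$has_location[i]
      )
      if (!is.na(p$polarity[i])) rec$polarity <- p$polarity[i]
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
    }
  }
  if (!is.null(labels_path)) {
    lab <- data.frame(
      user_id = vapply(users, `[[`, "", "user_id"),
      label = vapply(users, `[[`, 0L, "label")
    )
    utils::write.csv(lab[!is.na(lab$label), ], labels_path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a directory of term lists into a lexicon set
#'
#' Each UTF-8 file holds one term per line; the file stem names the category
#' (e.g. `sad.txt` -> category `sad`). Terms are trimmed and de-duplicated
#' (duplicate terms raise a warning and are kept once); an empty category file
#' is an error because rate features divide by lexicon membership tests.
#'
#' @param dir Directory of `*.txt` term lists.
#' @return A named list of character vectors, class `lexicon_set`.
#' @export
read_lexicons <- function(dir) {
  if (!dir.exists(dir)) stop("lexicon directory not found: ", dir)
  files <- list.files(dir, pattern = "\\.txt$", full.names = TRUE)
  if (!length(files)) stop("no .txt lexicon files in ", dir)
  cats <- lapply(files, function(f) {
    terms <- trimws(readLines(f, encoding = "UTF-8", warn = FALSE))
    terms <- terms[nzchar(terms)]
    if (!length(terms)) stop("empty lexicon file: ", f)
    if (anyDuplicated(terms)) {
      warning("duplicate terms in ", basename(f), "; keeping one copy")
      terms <- unique(terms)
    }
    terms
  })
  names(cats) <- sub("\\.txt$", "", basename(files))
  lexicon_set(cats)
}

#' Construct a lexicon set from a named list of term vectors
#'
#' @param categories Named list; each element a non-empty character vector of
#'   unique terms.
#' @return The validated list with class `lexicon_set`.
#' @export
lexicon_set <- function(categories) {
  stopifnot(is.list(categories), length(categories) > 0,
            !is.null(names(categories)), all(nzchar(names(categories))))
  categories <- lapply(categories, function(x) unique(as.character(x)))
  if (any(!lengths(categories))) stop("lexicon categories must be non-empty")
  structure(categories, class = "lexicon_set")
}

#' Write a lexicon set as a directory of term lists
#'
#' @param lexicons A `lexicon_set`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_lexicons <- function(lexicons, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(lexicons)) {
    writeLines(lexicons[[nm]], file.path(dir, paste0(nm, ".txt")),
               useBytes = TRUE)
  }
  invisible(dir)
}

#' Construct a per-user feature table
#'
#' @param x Numeric matrix, one row per user, named columns (features).
#' @param labels Integer vector of 0/1 labels (or `NA`), length `nrow(x)`.
#' @param user_ids Character vector of user ids; defaults to rownames of `x`.
#' @param groups Named character vector mapping each feature name to its
#'   group, `"textual"` or `"behavior"`.
#' @return An object of class `feature_table` with elements `x`, `labels`,
#'   `user_ids`, `groups`.
#' @export
feature_table <- function(x, labels = NULL, user_ids = NULL, groups = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) stop("feature matrix must have column names")
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (is.null(user_ids)) user_ids <- rownames(x) %||% sprintf("u%04d", seq_len(n))
  if (is.null(labels)) labels <- rep(NA_integer_, n)
  labels <- as.integer(labels)
  stopifnot(length(labels) == n, length(user_ids) == n)
  if (any(!is.na(labels) & !labels %in% c(0L, 1L))) {
    stop("labels must be 0, 1 or NA")
  }
  if (anyNA(x)) {
    warning("NaN/NA feature values replaced with 0")
    x[is.na(x)] <- 0
  }
  if (is.null(groups)) {
    groups <- stats::setNames(rep("textual", ncol(x)), colnames(x))
  }
  stopifnot(all(colnames(x) %in% names(groups)))
  rownames(x) <- user_ids
  structure(
    list(x = x, labels = labels, user_ids = as.character(user_ids),
         groups = groups[colnames(x)]),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table: %d users x %d features; %d depressed / %d control / %d unlabelled>\n",
              nrow(x$x), ncol(x$x),
              sum(x$labels == 1L, na.rm = TRUE),
              sum(x$labels == 0L, na.rm = TRUE),
              sum(is.na(x$labels))))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$x)

#' Subset the features (columns) of a feature table
#'
#' @param table A `feature_table`.
#' @param features Character vector of feature names to keep (order kept as
#'   in the table's schema) or a group name (`"textual"`/`"behavior"`).
#' @return A new `feature_table`.
#' @export
subset_features <- function(table, features) {
  stopifnot(inherits(table, "feature_table"))
  if (length(features) == 1L && features %in% c("textual", "behavior")) {
    features <- names(table$groups)[table$groups == features]
  }
  missing_f <- setdiff(features, colnames(table$x))
  if (length(missing_f)) {
    stop("unknown features: ", paste(missing_f, collapse = ", "))
  }
  keep <- colnames(table$x)[colnames(table$x) %in% features]
  feature_table(table$x[, keep, drop = FALSE], table$labels,
                table$user_ids, table$groups[keep])
}

#' Write / read a feature table as CSV
#'
#' The CSV layout is `user_id,label,<feature names...>`; values round-trip to
#' at least 10 decimal digits. On read, the `user_id` and `label` columns may
#' appear in either order but feature order is preserved as written.
#'
#' @param table A `feature_table`.
#' @param path CSV path.
#' @param groups Optional named group map to re-attach on read.
#' @return `write_feature_table`: `path` invisibly; `read_feature_table`: a
#'   `feature_table`.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- data.frame(user_id = table$user_ids, label = table$labels,
                   stringsAsFactors = FALSE)
  x <- table$x
  for (j in seq_len(ncol(x))) df[[colnames(x)[j]]] <- format(x[, j], digits = 15,
                                                             scientific = TRUE,
                                                             trim = TRUE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  # schema sidecar records the feature -> group map
  meta <- file.path(dirname(path),
                    paste0(sub("\\.csv$", "", basename(path)), ".schema.json"))
  jsonlite::write_json(as.list(table$groups), meta, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path, groups = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("user_id", "label") %in% names(df))) {
    stop("feature CSV must contain user_id and label columns")
  }
  feats <- setdiff(names(df), c("user_id", "label"))
  x <- as.matrix(df[, feats, drop = FALSE])
  storage.mode(x) <- "double"
  if (is.null(groups)) {
    meta <- file.path(dirname(path),
                      paste0(sub("\\.csv$", "", basename(path)), ".schema.json"))
    if (file.exists(meta)) {
      g <- jsonlite::read_json(meta, simplifyVector = TRUE)
      groups <- stats::setNames(unlist(g), names(g))
    }
  }
  feature_table(x, labels = df$label, user_ids = df$user_id, groups = groups)
}
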