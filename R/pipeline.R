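#' End-to-end pipeline driver
#'
#' Wires the stages — simulate, featurize, select, balance, train, score,
#' evaluate — over files on disk, with one master seed fanned out to
#' per-stage seeds so each stage is also reproducible standalone. Every
#' artifact gets a JSON provenance sidecar (package version, config, stage
#' seed).
#'
#' @param config Named list. Recognized keys: `stages` (character vector,
#'   default all of `simulate`, `featurize`, `select`, `balance`, `train`,
#'   `evaluate`), `out_dir` (required), `seed` (master seed, default 1),
#'   `posts_path`/`labels_path`/`lexicon_dir` (inputs when `simulate` is not
#'   run), `drop_fraction` (default 0.20), `k_smote` (default 5), `k_stack`
#'   (default 5), `cv_folds` (default 10), `test_fraction` (default 0.25),
#'   `tune` (default TRUE), `positive_class` (default 1), `scenario` (a
#'   [scenario_config()] for `simulate`).
#' @return Invisibly, a named list of artifact paths and in-memory results.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  stages_all <- c("simulate", "featurize", "select", "balance", "train",
                  "evaluate")
  stages <- cfg$stages %||% stages_all
  stopifnot(all(stages %in% stages_all), !is.null(cfg$out_dir))
  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed %||% 1L)
  res <- list()
  t_all <- Sys.time()

  provenance <- function(path, stage, stage_seed) {
    jsonlite::write_json(
      list(tool = "depstack",
           version = as.character(utils::packageVersion("depstack")),
           stage = stage, seed = stage_seed,
           written = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")),
      paste0(path, ".meta.json"), auto_unbox = TRUE)
  }
  stage_timer <- function(stage, expr) {
    t0 <- Sys.time()
    dep_log("stage ", stage, " started")
    out <- tryCatch(expr, error = function(e) {
      file.create(file.path(out_dir, paste0(stage, ".failed")))
      stop(sprintf("stage %s failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
    dep_log(sprintf("stage %s done in %.1fs", stage,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    out
  }

  if ("simulate" %in% stages) {
    res$corpus <- stage_timer("simulate", {
      s <- derive_seed(seed, "simulate")
      corpus <- generate_corpus(cfg$scenario %||% scenario_config(),
                                seed = s)
      posts_path <- file.path(out_dir, "posts.jsonl")
      labels_path <- file.path(out_dir, "labels.csv")
      write_posts(corpus$users, posts_path, labels_path)
      write_lexicons(corpus$lexicons, file.path(out_dir, "lexicons"))
      utils::write.csv(
        data.frame(token = names(corpus$tag_map),
                   pos = unname(corpus$tag_map)),
        file.path(out_dir, "tag_map.csv"), row.names = FALSE)
      provenance(posts_path, "simulate", s)
      cfg$posts_path <- posts_path
      cfg$labels_path <- labels_path
      cfg$lexicon_dir <- file.path(out_dir, "lexicons")
      corpus
    })
  }

  if ("featurize" %in% stages) {
    res$table <- stage_timer("featurize", {
      stopifnot(!is.null(cfg$posts_path), file.exists(cfg$posts_path))
      users <- read_posts(cfg$posts_path, cfg$labels_path)
      lex <- read_lexicons(cfg$lexicon_dir)
      tagger <- if (!is.null(res$corpus)) {
        fallback_tagger(res$corpus$tag_map)
      } else if (!is.null(cfg$tag_map_path)) {
        tm <- utils::read.csv(cfg$tag_map_path, stringsAsFactors = FALSE)
        fallback_tagger(stats::setNames(tm$pos, tm$token))
      } else {
        fallback_tagger()
      }
      tab <- build_feature_table(users, lex, tagger)
      path <- file.path(out_dir, "features.csv")
      write_feature_table(tab, path)
      provenance(path, "featurize", seed)
      tab
    })
  }

  if ("select" %in% stages) {
    res$selection <- stage_timer("select", {
      s <- derive_seed(seed, "select")
      sel <- fusion_select(res$table, cfg$drop_fraction %||% 0.20, seed = s)
      path <- file.path(out_dir, "features_selected.csv")
      write_feature_table(sel$table, path)
      utils::write.csv(sel$selection$ranking,
                       file.path(out_dir, "weights.csv"), row.names = FALSE)
      provenance(path, "select", s)
      res$table <- sel$table
      sel
    })
    res$table <- res$selection$table
  }

  if ("balance" %in% stages || "train" %in% stages || "evaluate" %in% stages) {
    split <- stratified_split(res$table$labels,
                              cfg$test_fraction %||% 0.25,
                              seed = derive_seed(seed, "split"))
    res$split <- split
  }

  if ("balance" %in% stages) {
    res$balanced <- stage_timer("balance", {
      s <- derive_seed(seed, "balance")
      train_tab <- feature_table(res$table$x[split$train, , drop = FALSE],
                                 res$table$labels[split$train],
                                 res$table$user_ids[split$train],
                                 res$table$groups)
      bal <- balance_table(train_tab, cfg$k_smote %||% 5L, seed = s)
      path <- file.path(out_dir, "features_train_balanced.csv")
      write_feature_table(bal, path)
      provenance(path, "balance", s)
      bal
    })
  }

  if ("train" %in% stages) {
    res$model <- stage_timer("train", {
      s <- derive_seed(seed, "train")
      tab <- res$balanced %||% res$table
      model <- fit_stacking(tab$x, tab$labels, k = cfg$k_stack %||% 5L,
                            seed = s)
      path <- file.path(out_dir, "scores_test.csv")
      scored <- predict(model, res$table$x[split$test, , drop = FALSE])
      utils::write.csv(
        cbind(user_id = res$table$user_ids[split$test], scored),
        path, row.names = FALSE)
      provenance(path, "train", s)
      model
    })
  }

  if ("evaluate" %in% stages) {
    res$report <- stage_timer("evaluate", {
      rep <- run_experiment(res$table, seed = seed,
                            test_fraction = cfg$test_fraction %||% 0.25,
                            cv_folds = cfg$cv_folds %||% 10L,
                            k_stack = cfg$k_stack %||% 5L,
                            k_smote = cfg$k_smote %||% 5L,
                            tune = cfg$tune %||% TRUE,
                            positive_class = cfg$positive_class %||% 1L)
      write_report(rep, file.path(out_dir, "report"))
      provenance(file.path(out_dir, "report"), "evaluate", seed)
      rep
    })
  }

  dep_log(sprintf("pipeline done in %.1fs",
                  as.numeric(difftime(Sys.time(), t_all, units = "secs"))))
  invisible(res)
}
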