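stage_seed <- function(seed, stage) {
  (as.integer(seed) + 1000003L * as.integer(stage)) %% 2147483647L
}

stage_abort <- function(stage, msg) {
  abort(paste0(stage, ": ", msg), class = "forumscope_stage_error")
}

#' Assemble a pipeline configuration from file paths
#'
#' Collects the input paths and analysis parameters of a full run. Paths
#' are checked up front so a missing input fails before any expensive
#' stage starts.
#'
#' @param corpus Path to the message corpus (CSV or JSONL).
#' @param background Path to the background corpus (one document per line).
#' @param annotations Path to the theme-annotation CSV.
#' @param users Optional path to the user table CSV.
#' @param lexicon_positive,lexicon_negative Optional lexicon paths
#'   (default: the bundled lexicon).
#' @param out_dir Output directory for report tables and the manifest.
#' @param k Top-k users per group per year.
#' @param years Years to cover (default: all years in the corpus).
#' @param embedding An [sgns_config()].
#' @param corpus_min_count Minimum forum-term frequency at the
#'   corpus-term stage.
#' @param min_positives Sparse-theme filter threshold.
#' @param folds Cross-validation folds.
#' @param seed Master seed; every stage derives its own seed from it.
#' @param decimals Decimal places for reported percentages.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(corpus, background, annotations, users = NULL,
                            lexicon_positive = NULL, lexicon_negative = NULL,
                            out_dir = NULL, k = 3, years = NULL,
                            embedding = sgns_config(), corpus_min_count = 5,
                            min_positives = 30, folds = 10, seed = 7,
                            decimals = 2) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; an
#' `embedding` mapping is passed to [sgns_config()]. Relative paths are
#' resolved against the YAML file's directory.
#'
#' @param path Path to the YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (startsWith(p, "/")) p else file.path(base, p)
  }
  do.call(pipeline_config, c(
    purrr::map(y[intersect(names(y), c("corpus", "background", "annotations",
                                       "users", "lexicon_positive",
                                       "lexicon_negative", "out_dir"))],
               resolve),
    y[intersect(names(y), c("k", "years", "corpus_min_count", "min_positives",
                            "folds", "seed", "decimals"))],
    list(embedding = do.call(sgns_config, as.list(y$embedding %||% list())))))
}

#' Run the full content-plus-frequency pipeline
#'
#' End-to-end orchestration: corpus ingest and validation, engagement
#' profiling and top-k group selection, abstinence-status inference, the
#' three-stage superposition embedding, sparse-theme filtering,
#' cross-validated per-theme classifiers, corpus-wide labeling, sentiment
#' scoring, and the group cross-tabulations (demographics, per-group
#' theme prevalence, per-group sentiment shares). Any stage failure
#' aborts with a stage-named error; all randomness derives from the one
#' master seed.
#'
#' @param config A [pipeline_config()] (file-based run), or `NULL` when
#'   the in-memory inputs below are supplied directly.
#' @param messages,users,background,annotations,lexicon In-memory inputs
#'   overriding file paths: a validated message tibble, user tibble,
#'   character background corpus, long annotation tibble, and a
#'   `sentiment_lexicon`.
#' @param out_dir Output directory; when non-`NULL` the report tables and
#'   run manifest are written there.
#' @param ... Parameters forwarded to [pipeline_config()] for in-memory
#'   runs (`k`, `years`, `embedding`, `min_positives`, `folds`, `seed`,
#'   ...).
#' @return An object of class `engage_run`: a list with the group
#'   assignments, summaries, theme report, label and sentiment tables,
#'   prevalence cross-tabulations, and the run `manifest`.
#' @export
run_pipeline <- function(config = NULL, messages = NULL, users = NULL,
                         background = NULL, annotations = NULL,
                         lexicon = NULL, out_dir = NULL, ...) {
  if (is.null(config)) {
    config <- pipeline_config(corpus = NA, background = NA, annotations = NA,
                              out_dir = out_dir, ...)
  }
  # -- ingest ---------------------------------------------------------------
  if (is.null(messages)) {
    for (p in c(corpus = config$corpus, background = config$background,
                annotations = config$annotations)) {
      if (!is.character(p) || !file.exists(p)) {
        stage_abort("ingest", paste0("missing input file: ", p))
      }
    }
    if (!is.null(config$users) && !file.exists(config$users)) {
      stage_abort("ingest", paste0("missing user table: ", config$users))
    }
    messages <- read_messages(config$corpus)
    users <- if (!is.null(config$users)) read_users(config$users)
    background <- readLines(config$background, encoding = "UTF-8")
    annotations <- read_annotations(config$annotations)
  } else {
    messages <- validate_messages(messages)
  }
  if (is.null(lexicon)) {
    lexicon <- if (!is.null(config$lexicon_positive)) {
      read_lexicon(config$lexicon_positive, config$lexicon_negative)
    } else default_lexicon()
  }
  if (is.null(annotations) || nrow(annotations) == 0L) {
    stage_abort("ingest", "no annotations supplied")
  }
  if (is.null(users)) {
    users <- forum_corpus(messages)$users
  }
  out_dir <- out_dir %||% config$out_dir
  seed <- config$seed

  # -- engagement -----------------------------------------------------------
  profiles <- compute_profiles(messages)
  years <- config$years %||% sort(unique(profiles$year))
  assignments <- engagement_groups(profiles, k = config$k, years = years)
  if (nrow(assignments) == 0L) stage_abort("engagement", "no users selected")
  statuses <- status_per_user_year(messages, users)
  demographics <- group_summary(assignments, users, statuses,
                                decimals = max(1, config$decimals - 1))

  # -- embeddings -----------------------------------------------------------
  emb_cfg <- config$embedding
  emb_cfg$seed <- stage_seed(seed, 1L)
  background_store <- train_background(background, emb_cfg)
  stage1 <- stage1_message_vectors(background_store, messages)
  corpus_terms <- corpus_term_vectors(stage1, messages,
                                      min_count = config$corpus_min_count)
  stage2 <- stage2_message_vectors(corpus_terms, messages)

  # -- classification -------------------------------------------------------
  missing_ann <- setdiff(unique(annotations$message_id), messages$message_id)
  if (length(missing_ann) > 0L) {
    stage_abort("classification",
                paste0("annotated message ids absent from corpus: ",
                       paste(utils::head(missing_ann, 3), collapse = ", ")))
  }
  theme_filter <- filter_themes(annotations,
                                min_positives = config$min_positives)
  theme_report <- cv_themes(stage2, annotations, theme_filter,
                            folds = config$folds, seed = stage_seed(seed, 2L))
  classifiers <- purrr::map(
    setNames(theme_filter$theme[theme_filter$retained],
             theme_filter$theme[theme_filter$retained]),
    ~ train_theme_classifier(stage2, annotations, .x))
  labels <- label_corpus(classifiers, stage2)
  prevalence <- theme_prevalence_by_group(
    labels, assignments, messages,
    themes = theme_filter$theme[theme_filter$retained],
    decimals = config$decimals)

  # -- sentiment ------------------------------------------------------------
  sentiment <- score_messages(messages, lexicon)
  sentiment_shares <- sentiment_by_group(sentiment, assignments, messages,
                                         decimals = config$decimals)

  # -- reporting ------------------------------------------------------------
  manifest <- list(
    package = as.character(utils::packageVersion("forumscope")),
    seed = seed,
    stage_seeds = list(embeddings = stage_seed(seed, 1L),
                       cross_validation = stage_seed(seed, 2L)),
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    n_messages = nrow(messages), n_users = nrow(users),
    n_annotated = length(unique(annotations$message_id)),
    years = years, k = config$k,
    n_slots = nrow(assignments),
    n_distinct_selected_users = dplyr::n_distinct(assignments$user_id),
    themes_retained = theme_filter$theme[theme_filter$retained],
    embedding = emb_cfg[c("dimension", "window", "negative", "epochs",
                          "min_count", "sample", "alpha", "seed")])

  run <- structure(
    list(profiles = profiles, assignments = assignments, statuses = statuses,
         demographics = demographics, theme_report = theme_report,
         labels = labels, prevalence = prevalence, sentiment = sentiment,
         sentiment_shares = sentiment_shares, stores = list(
           background = background_store, stage1 = stage1,
           corpus_terms = corpus_terms, stage2 = stage2),
         manifest = manifest),
    class = "engage_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' Write the report artifacts of a pipeline run
#'
#' Seven artifacts: group demographics, per-group theme prevalence,
#' per-group sentiment shares, the theme model report, per-message labels,
#' per-message sentiment, and the JSON run manifest. Every percentage in
#' the tables is reproducible from the per-message files via
#' [proportion()].
#'
#' @param run An `engage_run`.
#' @param out_dir Output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    demographics = file.path(out_dir, "group_demographics.csv"),
    prevalence = file.path(out_dir, "theme_prevalence.csv"),
    sentiment_shares = file.path(out_dir, "sentiment_shares.csv"),
    theme_report = file.path(out_dir, "theme_model_report.csv"),
    labels = file.path(out_dir, "message_labels.csv"),
    sentiment = file.path(out_dir, "message_sentiment.csv"),
    manifest = file.path(out_dir, "manifest.json"))
  readr::write_csv(tidy(run$demographics), paths[["demographics"]])
  readr::write_csv(run$prevalence, paths[["prevalence"]])
  readr::write_csv(run$sentiment_shares, paths[["sentiment_shares"]])
  readr::write_csv(tibble::as_tibble(run$theme_report), paths[["theme_report"]])
  readr::write_csv(run$labels, paths[["labels"]])
  readr::write_csv(run$sentiment, paths[["sentiment"]])
  jsonlite::write_json(run$manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' @export
print.engage_run <- function(x, ...) {
  cat("<engage_run> ", x$manifest$n_messages, " messages | ",
      x$manifest$n_slots, " top-k slots | ",
      length(x$manifest$themes_retained), " themes retained\n", sep = "")
  invisible(x)
}

#' @describeIn run_pipeline Glance method: one-row run summary (message,
#'   slot and theme counts plus macro/pooled classifier metrics).
#' @param x An `engage_run`.
#' @export
glance.engage_run <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(n_messages = x$manifest$n_messages,
                   n_slots = x$manifest$n_slots,
                   n_distinct_users = x$manifest$n_distinct_selected_users),
    glance(x$theme_report))
}
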