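RICH_THEMES <- c("goals_and_planning", "feedback_and_monitoring",
                 "social_support", "natural_consequences",
                 "comparison_of_behavior", "comparison_of_outcomes",
                 "rewards_and_threat", "self_belief")

ARCHETYPES <- c("initiator", "attractor", "poster", "background")

theme_token_sets <- function(taxonomy, tokens_per_theme = 10) {
  stems <- c(goals_and_planning = "goal", feedback_and_monitoring = "track",
             social_support = "supprt", shaping_knowledge = "knowhow",
             natural_consequences = "conseq", comparison_of_behavior = "compb",
             associations = "assoc", repetition_and_substitution = "substit",
             comparison_of_outcomes = "compo", rewards_and_threat = "rewrd",
             regulation = "regul", antecedents = "antec", identity = "identt",
             scheduled_consequences = "schedl", self_belief = "selfbl",
             covert_learning = "covrt")
  purrr::map(setNames(taxonomy, taxonomy), function(th) {
    stem <- stems[[th]] %||% substr(gsub("_", "", th), 1, 6)
    sprintf("%s%02d", stem, seq_len(tokens_per_theme))
  })
}

#' Synthetic forum generator configuration
#'
#' Describes the study conditions the generator emulates: a threaded
#' smoking-cessation community with four engagement archetypes
#' (thread-rooting initiators, reply-drawing attractors, high-volume
#' posters and a large background population), 16 behavior-change themes
#' of which 8 are deliberately sparse, theme-bearing token vocabularies,
#' Zipf-distributed filler vocabulary, community neologisms absent from
#' the background corpus, injected sentiment direction, and per-user quit
#' trajectories expressed as in-message quit-duration signatures.
#' Everything is deterministic under `seed`.
#'
#' @param seed Master seed for the generator.
#' @param n_users Number of users.
#' @param years Integer vector of calendar years covered.
#' @param archetype_mix Named fractions over the four archetypes
#'   (must sum to 1).
#' @param thread_rates,reply_rates Per-archetype Poisson rates of threads
#'   rooted and replies posted, per user per year.
#' @param reply_propensity Per-archetype weight with which a user's
#'   threads attract others' replies.
#' @param addressed_reply_prob Probability a reply names the thread root
#'   as explicit recipient (otherwise posted to the thread at large).
#' @param taxonomy Theme names; the first 8 rich/8 sparse split follows
#'   `rich_themes`.
#' @param rich_themes Themes given enough positives to survive the
#'   sparse-theme filter.
#' @param rich_per_message Rich themes carried by each message.
#' @param sparse_theme_prob Probability a message additionally carries one
#'   sparse theme.
#' @param tokens_per_theme Vocabulary size per theme.
#' @param n_filler Size of the shared filler vocabulary.
#' @param zipf_exponent Zipf rank-frequency exponent of the filler
#'   vocabulary.
#' @param filler_size,filler_mu Negative-binomial parameters of the filler
#'   token count per message (terse messages by default).
#' @param neologisms Tibble with columns `token`, `anchor_theme`, `rate`:
#'   community coinages that never enter the background corpus and are
#'   co-placed with tokens of their anchor theme in forum messages.
#' @param sentiment_mix Named positive/negative/neutral mixture of
#'   injected message sentiment.
#' @param n_sentiment_words Pool size of lexicon words used for injection.
#' @param quitter_frac Fraction of users with a quit trajectory; the rest
#'   have no abstinence signal at all.
#' @param logged_frac Fraction of quitters whose quit dates appear in the
#'   user event log (the rest are recoverable only from message
#'   signatures).
#' @param relapse_prob Probability a quitter has an earlier, brief,
#'   abandoned quit attempt in their history (its start date stays in the
#'   event log; no signatures are emitted between its relapse and the
#'   next quit).
#' @param quit_spread_days Final quit dates fall uniformly within this
#'   many days before the final year's end.
#' @param signature_prob Probability a message sent during an active quit
#'   attempt carries a quit-duration signature (the community tradition
#'   is to state it in essentially every message).
#' @param n_background_docs,background_theme_prob,background_doc_mu
#'   Background corpus: document count, share of documents built around a
#'   theme, mean document length in tokens.
#' @param planted_pairs List of length-2 character vectors planted to
#'   co-occur heavily in the background corpus (paraphrase-pair probes).
#' @param pair_doc_prob Probability a background document carries a
#'   planted pair.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(seed = 1010,
                         n_users = 100,
                         years = 2013:2014,
                         archetype_mix = c(initiator = 0.06, attractor = 0.06,
                                           poster = 0.06, background = 0.82),
                         thread_rates = c(initiator = 30, attractor = 4,
                                          poster = 6, background = 0.6),
                         reply_rates = c(initiator = 30, attractor = 21,
                                         poster = 104, background = 9),
                         reply_propensity = c(initiator = 1.5, attractor = 40,
                                              poster = 1.5, background = 1),
                         addressed_reply_prob = 0.7,
                         taxonomy = bct_taxonomy(),
                         rich_themes = RICH_THEMES,
                         rich_per_message = 3,
                         sparse_theme_prob = 0.12,
                         tokens_per_theme = 10,
                         n_filler = 2500,
                         zipf_exponent = 1.0,
                         filler_size = 6,
                         filler_mu = 14,
                         neologisms = tibble::tibble(
                           token = c("nicodemon", "sickarettes"),
                           anchor_theme = c("self_belief", "natural_consequences"),
                           rate = 0.3),
                         sentiment_mix = c(positive = 0.7, negative = 0.2,
                                           neutral = 0.1),
                         n_sentiment_words = 12,
                         quitter_frac = 0.85,
                         logged_frac = 0.576,
                         relapse_prob = 0.2,
                         quit_spread_days = 8 * 365,
                         signature_prob = 1.0,
                         n_background_docs = 2400,
                         background_theme_prob = 0.75,
                         background_doc_mu = 40,
                         planted_pairs = list(c("hammock", "relaxing")),
                         pair_doc_prob = 0.05) {
  cfg <- as.list(environment())
  if (abs(sum(archetype_mix) - 1) > 1e-8) {
    abort("archetype_mix fractions must sum to 1")
  }
  if (abs(sum(sentiment_mix) - 1) > 1e-8) {
    abort("sentiment_mix fractions must sum to 1")
  }
  if (any(c(thread_rates, reply_rates, reply_propensity) < 0)) {
    abort("rates must be non-negative")
  }
  if (!all(rich_themes %in% taxonomy)) abort("rich_themes must lie in taxonomy")
  if (n_filler < 1 || tokens_per_theme < 1) abort("vocabulary must be non-empty")
  cfg$theme_tokens <- theme_token_sets(taxonomy, tokens_per_theme)
  cfg$filler_tokens <- sprintf("fill%03d", seq_len(n_filler))
  bg_vocab <- c(unlist(cfg$theme_tokens), cfg$filler_tokens,
                unlist(planted_pairs))
  if (any(neologisms$token %in% bg_vocab)) {
    abort("neologisms must be absent from the background vocabulary")
  }
  # archetype-favored rich themes drive the per-group content contrasts
  cfg$theme_preferences <- list(
    initiator = c("rewards_and_threat", "social_support"),
    attractor = c("goals_and_planning", "comparison_of_outcomes"),
    poster = c("feedback_and_monitoring", "goals_and_planning"),
    background = character())
  structure(cfg, class = "synth_config")
}

zipf_probs <- function(n, s) {
  p <- seq_len(n)^(-s)
  p / sum(p)
}

#' Generate a synthetic background corpus
#'
#' Documents (one per line) in which each theme's token set co-occurs
#' within short windows, over a Zipf-distributed filler vocabulary, so
#' skip-gram training can learn theme-coherent neighborhoods. Planted
#' paraphrase pairs co-occur heavily; configured neologisms never appear.
#' Byte-identical output under a fixed seed.
#'
#' @param config A [synth_config()].
#' @return Character vector of documents.
#' @export
generate_background <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed + 1L, {
    fill_p <- zipf_probs(config$n_filler, config$zipf_exponent)
    themes <- names(config$theme_tokens)
    purrr::map_chr(seq_len(config$n_background_docs), function(i) {
      n_fill <- rnbinom(1, size = 8, mu = config$background_doc_mu)
      toks <- sample(config$filler_tokens, n_fill, replace = TRUE, prob = fill_p)
      if (runif(1) < config$background_theme_prob) {
        th <- sample(themes, 1)
        n_th <- 8 + rpois(1, 4)
        toks <- c(toks, sample(config$theme_tokens[[th]], n_th, replace = TRUE))
      }
      toks <- sample(toks)
      if (length(config$planted_pairs) > 0L && runif(1) < config$pair_doc_prob) {
        pair <- config$planted_pairs[[sample.int(length(config$planted_pairs), 1)]]
        pos <- sample.int(length(toks) + 1L, 1L) - 1L
        toks <- append(toks, rep(pair, 4), after = pos)
      }
      paste(toks, collapse = " ")
    })
  })
}

sample_archetypes <- function(config) {
  counts <- diff(c(0, round(cumsum(config$archetype_mix) * config$n_users)))
  rep(ARCHETYPES, counts)
}

sample_message_themes <- function(config, archetype) {
  w <- rep(1, length(config$rich_themes))
  names(w) <- config$rich_themes
  w[config$theme_preferences[[archetype]]] <- 2
  rich <- sample(config$rich_themes, config$rich_per_message, prob = w)
  sparse_pool <- setdiff(config$taxonomy, config$rich_themes)
  if (length(sparse_pool) > 0L && runif(1) < config$sparse_theme_prob) {
    c(rich, sample(sparse_pool, 1))
  } else rich
}

quit_signature <- function(days) {
  if (runif(1) < 0.6) {
    sprintf("////%d days, %d hours, %d minutes and %d seconds smoke free.",
            days, sample.int(24, 1) - 1L, sample.int(60, 1) - 1L,
            sample.int(60, 1) - 1L)
  } else {
    sprintf("%d days smoke free", days)
  }
}

#' Generate a synthetic threaded forum corpus with ground truth
#'
#' Builds users with archetypes and quit trajectories, roots threads and
#' attaches replies according to the archetype rates, and assembles each
#' message body from its true theme tokens, Zipfian filler, optional
#' neologisms co-placed with their anchor-theme tokens, injected sentiment
#' words, and a quit-duration signature consistent with the sender's
#' trajectory. The emitted ground truth covers per-message themes and
#' sentiment, per-user archetype and quit history, and the per-user-year
#' abstinence status derivable at each year's end.
#'
#' @param config A [synth_config()].
#' @return A list of class `synth_forum` with elements `messages`,
#'   `users` (event log only for logged quitters), and `truth`
#'   (`message_truth`, `user_truth`, `status_truth`).
#' @export
generate_forum <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (length(unlist(config$theme_tokens)) == 0L || config$n_filler == 0L) {
    abort("infeasible config: empty vocabulary")
  }
  withr::with_seed(config$seed + 2L, {
    users <- generate_users(config)
    skeleton <- generate_thread_skeleton(config, users)
    bodies <- generate_bodies(config, users, skeleton)
    messages <- validate_messages(dplyr::select(
      bodies, "message_id", "thread_id", "sender_id", "recipient_id",
      "timestamp", "body"))
    status_truth <- true_status_grid(config, users, messages)
    user_table <- users |>
      dplyr::mutate(quit_dates = purrr::map2(.data$quit_dates_true, .data$logged,
                                             ~ if (.y) .x else as.Date(character()))) |>
      dplyr::select("user_id", "age", "gender", "quit_dates")
    truth <- list(
      message_truth = dplyr::select(bodies, "message_id", "themes",
                                    "sentiment", "neologism"),
      user_truth = dplyr::select(users, "user_id", "archetype", "logged",
                                 "quit_dates_true", "quit_attempts"),
      status_truth = status_truth)
    structure(list(messages = messages, users = validate_users(user_table),
                   truth = truth, config = config),
              class = "synth_forum")
  })
}

generate_users <- function(config) {
  n <- config$n_users
  arch <- sample_archetypes(config)
  horizon <- as.Date(paste0(max(config$years), "-12-31"))
  is_quitter <- runif(n) < config$quitter_frac
  # each quit attempt is a window [start, end); the final attempt is open.
  # signatures only exist inside an active window: a relapsed user's
  # counter disappears until the next quit date is set.
  attempts <- purrr::map(seq_len(n), function(i) {
    if (!is_quitter[i]) {
      return(tibble::tibble(start = as.Date(character()),
                            end = as.Date(character())))
    }
    final <- horizon - sample.int(config$quit_spread_days, 1) - 9L
    if (runif(1) < config$relapse_prob) {
      gap <- sample(30:180, 1)
      dur <- sample(5:28, 1)
      tibble::tibble(start = c(final - gap, final),
                     end = c(final - gap + min(dur, gap - 1L), as.Date(NA)))
    } else {
      tibble::tibble(start = final, end = as.Date(NA))
    }
  })
  tibble::tibble(
    user_id = sprintf("u%04d", seq_len(n)),
    archetype = arch,
    age = pmin(80L, pmax(18L, as.integer(round(stats::rnorm(n, 49, 9.4))))),
    gender = sample(c("female", "male", "other/unknown"), n, replace = TRUE,
                    prob = c(0.78, 0.18, 0.04)),
    quit_attempts = attempts,
    quit_dates_true = purrr::map(attempts, ~ sort(.x$start)),
    logged = is_quitter & runif(n) < config$logged_frac)
}

# days smoke free at time t, or NA when no quit attempt is active
active_attempt_days <- function(attempts, t) {
  t_date <- as.Date(t)
  live <- attempts$start <= t_date &
    (is.na(attempts$end) | t_date < attempts$end)
  if (!any(live)) return(NA_real_)
  start <- max(attempts$start[live])
  floor(as.numeric(difftime(t, as.POSIXct(start, tz = "UTC"), units = "days")))
}

generate_thread_skeleton <- function(config, users) {
  rows <- purrr::map(config$years, function(y) {
    y_start <- as.POSIXct(paste0(y, "-01-01 00:00:00"), tz = "UTC")
    y_end <- as.POSIXct(paste0(y, "-12-31 23:59:59"), tz = "UTC")
    span <- as.numeric(difftime(y_end, y_start, units = "secs"))
    n_roots <- rpois(nrow(users), config$thread_rates[users$archetype])
    n_replies <- rpois(nrow(users), config$reply_rates[users$archetype])
    if (sum(n_roots) == 0L) n_roots[which.max(n_replies)] <- 1L
    roots <- tibble::tibble(
      sender_id = rep(users$user_id, n_roots),
      root_arch = rep(users$archetype, n_roots),
      timestamp = y_start + runif(sum(n_roots), 0, span * 0.96),
      is_root = TRUE)
    roots$thread_key <- paste0(y, "_", seq_len(nrow(roots)))
    weights <- config$reply_propensity[roots$root_arch]
    reply_sender <- rep(users$user_id, n_replies)
    tgt <- sample.int(nrow(roots), length(reply_sender), replace = TRUE,
                      prob = weights)
    root_t <- as.numeric(roots$timestamp[tgt])
    lag <- rexp(length(tgt), rate = 1 / (48 * 3600))
    over <- root_t + lag > as.numeric(y_end)
    lag[over] <- runif(sum(over), 0, as.numeric(y_end) - root_t[over])
    replies <- tibble::tibble(
      sender_id = reply_sender,
      root_arch = roots$root_arch[tgt],
      timestamp = as.POSIXct(root_t + pmax(lag, 1), tz = "UTC",
                             origin = "1970-01-01"),
      is_root = FALSE,
      thread_key = roots$thread_key[tgt],
      recipient_id = ifelse(runif(length(tgt)) < config$addressed_reply_prob,
                            roots$sender_id[tgt], NA_character_))
    roots$recipient_id <- NA_character_
    dplyr::bind_rows(roots, replies)
  }) |> purrr::list_rbind()

  rows <- dplyr::arrange(rows, .data$timestamp)
  rows$message_id <- sprintf("m%06d", seq_len(nrow(rows)))
  thread_ids <- setNames(sprintf("t%05d", seq_along(unique(rows$thread_key))),
                         unique(rows$thread_key))
  rows$thread_id <- unname(thread_ids[rows$thread_key])
  rows
}

generate_bodies <- function(config, users, skeleton) {
  fill_p <- zipf_probs(config$n_filler, config$zipf_exponent)
  lexicon <- default_lexicon()
  pos_pool <- utils::head(sort(lexicon$positive), config$n_sentiment_words)
  neg_pool <- utils::head(sort(lexicon$negative), config$n_sentiment_words)
  user_idx <- setNames(seq_len(nrow(users)), users$user_id)
  n <- nrow(skeleton)
  sentiments <- sample(names(config$sentiment_mix), n, replace = TRUE,
                       prob = config$sentiment_mix)
  out_themes <- vector("list", n)
  out_body <- character(n)
  out_neo <- character(n)
  for (i in seq_len(n)) {
    u <- users[user_idx[[skeleton$sender_id[i]]], ]
    themes <- sample_message_themes(config, u$archetype)
    toks <- unlist(purrr::map(themes, function(th) {
      pool <- config$theme_tokens[[th]]
      sample(pool, min(length(pool), 3 + rpois(1, 1.2)))
    }))
    n_fill <- rnbinom(1, size = config$filler_size, mu = config$filler_mu)
    toks <- c(toks, sample(config$filler_tokens, n_fill, replace = TRUE,
                           prob = fill_p))
    neo <- NA_character_
    for (j in which(config$neologisms$anchor_theme %in% themes)) {
      if (runif(1) < config$neologisms$rate[j]) {
        # the coinage substitutes for its concept, so it rides along with a
        # solid block of the concept vocabulary
        neo <- config$neologisms$token[j]
        toks <- c(toks, neo,
                  sample(config$theme_tokens[[config$neologisms$anchor_theme[j]]], 4))
      }
    }
    sent <- sentiments[i]
    if (sent == "positive") {
      toks <- c(toks, sample(pos_pool, min(length(pos_pool), 1 + rpois(1, 0.8))))
    } else if (sent == "negative") {
      toks <- c(toks, sample(neg_pool, min(length(neg_pool), 1 + rpois(1, 0.8))))
    }
    toks <- sample(toks)
    caps <- runif(length(toks)) < 0.08
    toks[caps] <- stringr::str_to_title(toks[caps])
    body <- paste(toks, collapse = " ")
    days <- active_attempt_days(u$quit_attempts[[1]], skeleton$timestamp[i])
    if (!is.na(days) && runif(1) < config$signature_prob) {
      body <- paste0(body, " ", quit_signature(days))
    }
    out_themes[[i]] <- sort(themes)
    out_body[i] <- body
    out_neo[i] <- neo
  }
  skeleton |>
    dplyr::mutate(body = out_body, themes = out_themes,
                  sentiment = factor(sentiments,
                                     levels = c("positive", "negative", "neutral")),
                  neologism = out_neo)
}

true_status_grid <- function(config, users, messages) {
  grid <- tidyr::expand_grid(user_id = users$user_id, year = config$years)
  grid |>
    dplyr::left_join(dplyr::select(users, "user_id", "quit_attempts"),
                     by = "user_id") |>
    dplyr::mutate(
      anchor = as.Date(paste0(.data$year, "-12-31")),
      days = purrr::map2_dbl(.data$quit_attempts, .data$anchor, function(at, a) {
        if (nrow(at) == 0L) return(NA_real_)
        live <- at$start <= a & (is.na(at$end) | a < at$end)
        if (!any(live)) return(NA_real_)
        as.numeric(a - max(at$start[live]))
      }),
      smoking = purrr::map2_lgl(.data$quit_attempts, .data$anchor, function(at, a) {
        # between an abandoned attempt and the next quit date
        nrow(at) > 0L && any(at$start <= a) &&
          !any(at$start <= a & (is.na(at$end) | a < at$end))
      }),
      status = bin_abstinence(.data$days, .data$smoking)) |>
    dplyr::select("user_id", "year", "days", "smoking", "status")
}

#' @export
print.synth_forum <- function(x, ...) {
  cat("<synth_forum> ", nrow(x$messages), " messages, ", nrow(x$users),
      " users, years ", paste(range(x$config$years), collapse = "-"), "\n",
      sep = "")
  invisible(x)
}

#' Write a synthetic bundle to disk in the package's exchange formats
#'
#' Emits the corpus (CSV or JSONL), the user table, the background corpus
#' as plain text, the annotation subset, the ground truth as JSONL, and
#' the configuration as YAML.
#'
#' @param fixture A fixture list from [default_study_fixture()] (or a
#'   compatible list).
#' @param dir Output directory (created if needed).
#' @param corpus_format `"csv"` or `"jsonl"`.
#' @return Named character vector of the files written, invisibly.
#' @export
write_synthetic_bundle <- function(fixture, dir, corpus_format = "csv") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (corpus_format == "jsonl") "jsonl" else "csv"
  paths <- c(
    messages = file.path(dir, paste0("messages.", ext)),
    users = file.path(dir, "users.csv"),
    background = file.path(dir, "background.txt"),
    annotations = file.path(dir, "annotations.csv"),
    truth = file.path(dir, "ground_truth.jsonl"),
    config = file.path(dir, "config.yaml"))
  write_messages(fixture$messages, paths[["messages"]], format = corpus_format)
  write_users(fixture$users, paths[["users"]])
  writeLines(fixture$background, paths[["background"]])
  write_annotations(fixture$annotations, paths[["annotations"]])
  truth_lines <- purrr::pmap_chr(
    fixture$truth$message_truth,
    function(message_id, themes, sentiment, neologism) {
      jsonlite::toJSON(list(message_id = message_id, themes = themes,
                            sentiment = as.character(sentiment),
                            neologism = if (is.na(neologism)) NULL else neologism),
                       auto_unbox = TRUE, null = "null")
    })
  writeLines(truth_lines, paths[["truth"]])
  cfg <- unclass(fixture$config)
  cfg$neologisms <- as.list(as.data.frame(fixture$config$neologisms))
  yaml::write_yaml(cfg, paths[["config"]])
  invisible(paths)
}

#' Default end-to-end study fixture
#'
#' A small, fully labeled bundle exercising every pipeline stage: a
#' two-year corpus of roughly 3,000 messages from 100 users, all 16
#' taxonomy themes with 8 deliberately sparse, an annotation subset of
#' 200 messages, the bundled sentiment lexicon, and a background corpus
#' of roughly 100k tokens. Runs through the full pipeline in minutes on
#' one CPU.
#'
#' @param seed Master seed (propagated to the generator config).
#' @return A list with `config`, `messages`, `users`, `truth`,
#'   `annotations` (long tibble over 200 messages), `background`, and
#'   `lexicon`.
#' @export
default_study_fixture <- function(seed = 1010) {
  config <- synth_config(seed = seed)
  background <- generate_background(config)
  forum <- generate_forum(config)
  annotations <- withr::with_seed(config$seed + 3L, {
    ids <- sample(forum$messages$message_id, 200)
    forum$truth$message_truth |>
      dplyr::filter(.data$message_id %in% ids) |>
      dplyr::select("message_id", theme = "themes") |>
      tidyr::unnest("theme")
  })
  list(config = config, messages = forum$messages, users = forum$users,
       truth = forum$truth, annotations = annotations,
       background = background, lexicon = default_lexicon(),
       stopwords = fixture_stopwords(config))
}

#' @describeIn default_study_fixture The stopword list recommended for the
#'   fixture's embedding stages: the high-frequency head of the filler
#'   vocabulary (the generator's function-word analogue) plus the
#'   quit-signature boilerplate words that occur in nearly every message.
#' @param config A [synth_config()].
#' @export
fixture_stopwords <- function(config) {
  c(utils::head(config$filler_tokens, 250),
    "days", "day", "hours", "hour", "minutes", "minute",
    "seconds", "second", "smoke", "free")
}
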