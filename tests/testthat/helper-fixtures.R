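# Shared fixtures, built once per test run. The default study fixture and
# its embedding stores are the expensive pieces; everything else is cheap.

.fx_env <- new.env(parent = emptyenv())

study_fixture <- function() {
  if (is.null(.fx_env$fx)) .fx_env$fx <- default_study_fixture(seed = 1010)
  .fx_env$fx
}

fixture_stores <- function() {
  if (is.null(.fx_env$stores)) {
    fx <- study_fixture()
    bg <- train_background(fx$background,
                           sgns_config(seed = 42, stopwords = fx$stopwords))
    s1 <- stage1_message_vectors(bg, fx$messages)
    ct <- corpus_term_vectors(s1, fx$messages)
    s2 <- stage2_message_vectors(ct, fx$messages)
    .fx_env$stores <- list(background = bg, stage1 = s1,
                           corpus_terms = ct, stage2 = s2)
  }
  .fx_env$stores
}

# small corpus for cheap structural tests
small_forum <- function() {
  if (is.null(.fx_env$small)) {
    cfg <- synth_config(seed = 33, n_users = 30, years = 2014,
                        n_background_docs = 60)
    .fx_env$small <- generate_forum(cfg)
  }
  .fx_env$small
}

# hand-built message tibble; timestamps spaced one hour apart
make_messages <- function(ids, thread, sender, recipient = NA_character_,
                          body = "hello world", year = 2014) {
  n <- length(ids)
  tibble::tibble(
    message_id = ids,
    thread_id = rep_len(thread, n),
    sender_id = rep_len(sender, n),
    recipient_id = rep_len(recipient, n),
    timestamp = as.POSIXct(paste0(year, "-06-01 08:00:00"), tz = "UTC") +
      3600 * seq_len(n),
    body = rep_len(body, n))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
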