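#' Load a sentiment lexicon
#'
#' Two plain-text word lists, one token per line (`#` comments and blank
#' lines ignored). The positive and negative sets must be non-empty and
#' disjoint.
#'
#' @param positive_path,negative_path Paths to the word lists.
#' @return An object of class `sentiment_lexicon`: a list with `positive`
#'   and `negative` character vectors.
#' @export
read_lexicon <- function(positive_path, negative_path) {
  read_words <- function(p) {
    if (!file.exists(p)) abort(paste0("lexicon file not found: ", p))
    w <- trimws(readLines(p, encoding = "UTF-8"))
    unique(tolower(w[nzchar(w) & !startsWith(w, "#")]))
  }
  sentiment_lexicon(read_words(positive_path), read_words(negative_path))
}

#' @describeIn read_lexicon Construct a lexicon from in-memory word sets.
#' @param positive,negative Character vectors of tokens.
#' @export
sentiment_lexicon <- function(positive, negative) {
  positive <- unique(tolower(positive))
  negative <- unique(tolower(negative))
  if (length(positive) == 0L || length(negative) == 0L) {
    abort("lexicon word sets must be non-empty")
  }
  clash <- intersect(positive, negative)
  if (length(clash) > 0L) {
    abort(paste0("lexicon sets overlap: ", paste(utils::head(clash, 5), collapse = ", ")))
  }
  structure(list(positive = positive, negative = negative),
            class = "sentiment_lexicon")
}

#' @describeIn read_lexicon The lexicon bundled with the package: a small
#'   general-purpose word list shipped as plain text under `extdata`.
#' @export
default_lexicon <- function() {
  read_lexicon(
    system.file("extdata", "lexicon_positive.txt", package = "forumscope"),
    system.file("extdata", "lexicon_negative.txt", package = "forumscope"))
}

#' @export
print.sentiment_lexicon <- function(x, ...) {
  cat("<sentiment_lexicon> ", length(x$positive), " positive / ",
      length(x$negative), " negative terms\n", sep = "")
  invisible(x)
}

#' Score message sentiment against a lexicon
#'
#' Dictionary ratio score: (positive-token hits minus negative-token hits)
#' divided by the total token count, giving a score in `[-1, 1]`; the
#' direction is its sign (zero maps to neutral). Empty messages and
#' messages without any lexicon token score 0. No negation or valence
#' shifting is applied.
#'
#' @param messages Message tibble (columns `message_id`, `body`), or a
#'   character vector of bodies.
#' @param lexicon A `sentiment_lexicon` (default: the bundled one).
#' @param stopwords Stopword list passed to the tokenizer.
#' @return Tibble `message_id`, `n_tokens`, `n_positive`, `n_negative`,
#'   `score`, `direction` (factor positive/negative/neutral).
#' @export
score_messages <- function(messages, lexicon = default_lexicon(),
                           stopwords = character()) {
  if (is.character(messages)) {
    messages <- tibble::tibble(
      message_id = sprintf("m%d", seq_along(messages)), body = messages)
  }
  toks <- tokenize(messages$body, stopwords = stopwords)
  n_tok <- purrr::map_int(toks, length)
  n_pos <- purrr::map_int(toks, ~ sum(.x %in% lexicon$positive))
  n_neg <- purrr::map_int(toks, ~ sum(.x %in% lexicon$negative))
  score <- ifelse(n_tok > 0, (n_pos - n_neg) / n_tok, 0)
  tibble::tibble(
    message_id = messages$message_id,
    n_tokens = n_tok, n_positive = n_pos, n_negative = n_neg,
    score = score,
    direction = factor(
      dplyr::case_when(score > 0 ~ "positive", score < 0 ~ "negative",
                       TRUE ~ "neutral"),
      levels = c("positive", "negative", "neutral")))
}

#' Sentiment direction shares per engagement group
#'
#' Positive/negative/neutral shares over each group's message denominator
#' (all messages sent by the group's selected user-year slots). The three
#' shares sum to 100 up to the rounding slack of the shared
#' [proportion()] rule.
#'
#' @param results Sentiment tibble from [score_messages()].
#' @param assignments Group assignments from [engagement_groups()].
#' @param messages The message tibble.
#' @param decimals Decimal places for percentages.
#' @return Tibble `group`, `direction`, `n`, `denominator`, `pct`.
#' @export
sentiment_by_group <- function(results, assignments, messages, decimals = 2) {
  gm <- group_messages(assignments, messages)
  if (nrow(gm) == 0L) {
    warn("no group has any message; empty sentiment table")
    return(tibble::tibble(group = character(), direction = character(),
                          n = integer(), denominator = integer(),
                          pct = numeric()))
  }
  denom <- gm |> dplyr::count(.data$group, name = "denominator")
  gm |>
    dplyr::inner_join(dplyr::select(results, "message_id", "direction"),
                      by = "message_id", relationship = "many-to-many") |>
    dplyr::count(.data$group, .data$direction, .drop = FALSE, name = "n") |>
    dplyr::left_join(denom, by = "group") |>
    dplyr::mutate(pct = proportion(.data$n, .data$denominator, decimals)) |>
    dplyr::arrange(.data$group, .data$direction)
}
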