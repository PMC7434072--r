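#' Tokenize message or document text
#'
#' Lowercases, splits on runs of non-alphanumeric characters, drops tokens
#' shorter than two characters, and removes stopwords. The same tokenizer is
#' used for the background corpus, all three superposition stages, and
#' sentiment scoring, so that vocabularies line up across pipeline stages.
#'
#' @param text Character vector of texts.
#' @param stopwords Character vector of tokens to remove (default none).
#' @param drop_numeric Drop tokens consisting entirely of digits (useful
#'   for embedding vocabularies, where free-standing numbers such as
#'   quit-counter values carry no stable distributional meaning; default
#'   `FALSE`).
#' @return A list with one character vector of tokens per element of `text`.
#' @examples
#' tokenize(c("Nicodemon!!", "13 days smoke free"))
#' @export
tokenize <- function(text, stopwords = character(), drop_numeric = FALSE) {
  text <- tolower(as.character(text))
  toks <- stringr::str_split(text, "[^a-z0-9]+")
  purrr::map(toks, function(t) {
    t <- t[nchar(t) >= 2L]
    if (drop_numeric) t <- t[!grepl("^[0-9]+$", t)]
    if (length(stopwords) > 0L) t <- t[!t %in% stopwords]
    t
  })
}
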