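#' Skip-gram negative-sampling configuration
#'
#' Training settings for the background term embeddings. The defaults
#' follow the reference skip-gram recipe (window 5, 5 negative samples,
#' 5 epochs, minimum token frequency 5, subsampling threshold 1e-3);
#' only the dimensionality is a substantive modeling choice — 500 for
#' full-scale corpora, 50 by default here so desk-scale corpora train in
#' seconds without materially changing neighborhood structure.
#'
#' @param dimension Embedding dimensionality.
#' @param window Maximum context window (dynamically shrunk per position).
#' @param negative Negative samples per positive example.
#' @param epochs Training passes over the corpus.
#' @param min_count Minimum token frequency to enter the vocabulary.
#' @param sample Frequent-word subsampling threshold.
#' @param alpha Initial learning rate (linear decay).
#' @param seed Integer RNG seed; recorded in the store's config.
#' @param stopwords Stopword list applied by the tokenizer, identically in
#'   the background corpus and all forum superposition stages.
#' @param drop_numeric Exclude free-standing number tokens from embedding
#'   vocabularies (default `TRUE`; quit-counter values and similar digits
#'   have no stable distributional meaning).
#' @return An object of class `sgns_config`.
#' @export
sgns_config <- function(dimension = 50, window = 5, negative = 5, epochs = 5,
                        min_count = 5, sample = 1e-3, alpha = 0.025,
                        seed = 1, stopwords = character(),
                        drop_numeric = TRUE) {
  cfg <- list(dimension = as.integer(dimension), window = as.integer(window),
              negative = as.integer(negative), epochs = as.integer(epochs),
              min_count = as.integer(min_count), sample = sample,
              alpha = alpha, seed = as.integer(seed), stopwords = stopwords,
              drop_numeric = isTRUE(drop_numeric))
  num <- cfg[c("dimension", "window", "negative", "epochs", "min_count",
               "sample", "alpha")]
  if (any(unlist(num) <= 0 & names(num) != "sample") || cfg$sample < 0) {
    abort("all sgns_config settings must be positive (sample may be 0)")
  }
  structure(cfg, class = "sgns_config")
}

#' Train background term embeddings with skip-gram negative sampling
#'
#' Learns one vector per vocabulary term from a large unannotated
#' background corpus (one document per line), so that terms occurring in
#' similar contexts receive similar vectors. These vectors carry general
#' distributional knowledge into the forum corpus, whose terse messages
#' are too short to train a distributional model on their own. Training
#' is single-threaded and deterministic given the seed.
#'
#' @param background Character vector of documents, or the path of a
#'   plain-text file with one document per line.
#' @param config An [sgns_config()].
#' @return A `vector_store` with provenance `"background_terms"`, one
#'   unit-norm row per retained vocabulary term.
#' @export
train_background <- function(background, config = sgns_config()) {
  stopifnot(inherits(config, "sgns_config"))
  if (length(background) == 1L && file.exists(background)) {
    background <- readLines(background, encoding = "UTF-8")
  }
  toks <- tokenize(background, stopwords = config$stopwords,
                   drop_numeric = config$drop_numeric)
  counts <- table(unlist(toks))
  counts <- counts[counts >= config$min_count]
  if (length(counts) == 0L) {
    abort("background vocabulary is empty after min_count filtering")
  }
  vocab <- names(counts)
  idx <- setNames(seq_along(vocab) - 1L, vocab)
  sequences <- purrr::map(toks, function(t) {
    unname(idx[t[t %in% vocab]])
  })
  sequences <- sequences[purrr::map_int(sequences, length) > 1L]

  mat <- .cpp_train_sgns(sequences, as.numeric(counts), config$dimension,
                         config$window, config$negative, config$epochs,
                         config$alpha, config$sample, config$seed)
  rownames(mat) <- vocab
  vector_store(normalize_rows(mat), provenance = "background_terms",
               config = unclass(config))
}

# sparse token-incidence matrix over the given vocabulary;
# binary = presence semantics, otherwise occurrence counts
incidence_matrix <- function(token_lists, ids, vocab, binary = FALSE) {
  idx <- setNames(seq_along(vocab), vocab)
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  for (i in seq_along(token_lists)) {
    t <- token_lists[[i]]
    t <- t[t %in% vocab]
    if (length(t) == 0L) next
    tab <- table(t)
    rows <- c(rows, rep.int(i, length(tab)))
    cols <- c(cols, unname(idx[names(tab)]))
    vals <- c(vals, if (binary) rep.int(1, length(tab)) else as.numeric(tab))
  }
  Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                       dims = c(length(token_lists), length(vocab)),
                       dimnames = list(ids, vocab))
}

#' Stage-1 message vectors: superpose background term vectors
#'
#' First superposition stage: each message's vector is the sum of the
#' background vectors of its in-vocabulary tokens (counting multiplicity),
#' unit-normalized. Tokens absent from the background vocabulary are
#' skipped; messages with no in-vocabulary token get an all-zero vector
#' and are flagged.
#'
#' @param background Background `vector_store` from [train_background()].
#' @param messages Validated message tibble.
#' @param stopwords Stopword list; must match the one used in training
#'   (taken from the store's config by default).
#' @return A `vector_store` with provenance `"stage1_messages"`, one row
#'   per message id.
#' @export
stage1_message_vectors <- function(background, messages, stopwords = NULL) {
  cfg <- attr(background, "config")
  stopwords <- stopwords %||% cfg$stopwords %||% character()
  toks <- tokenize(messages$body, stopwords = stopwords,
                   drop_numeric = cfg$drop_numeric %||% FALSE)
  inc <- incidence_matrix(toks, messages$message_id, rownames(background))
  mat <- as.matrix(inc %*% unclass(background))
  flagged <- rownames(mat)[sqrt(rowSums(mat^2)) == 0]
  vector_store(normalize_rows(mat), provenance = "stage1_messages",
               config = attr(background, "config"), flagged = flagged)
}

#' Corpus-adapted term vectors: superpose stage-1 message vectors
#'
#' Second stage: each forum term's vector is the sum of the stage-1
#' vectors of the messages in which the term occurs (presence, not
#' multiplicity), unit-normalized. Every forum token meeting the minimum
#' frequency gets a vector — including community neologisms absent from
#' the background vocabulary, which acquire meaning from the background
#' representations of their co-occurring terms.
#'
#' @param stage1 Stage-1 `vector_store`.
#' @param messages The same message tibble the stage-1 store was built on.
#' @param min_count Minimum forum-corpus frequency for a term vector.
#' @param stopwords Stopword list (defaults to the store's config).
#' @return A `vector_store` with provenance `"corpus_terms"`.
#' @export
corpus_term_vectors <- function(stage1, messages, min_count = 5,
                                stopwords = NULL) {
  cfg <- attr(stage1, "config")
  stopwords <- stopwords %||% cfg$stopwords %||% character()
  toks <- tokenize(messages$body, stopwords = stopwords,
                   drop_numeric = cfg$drop_numeric %||% FALSE)
  counts <- table(unlist(toks))
  vocab <- names(counts[counts >= min_count])
  if (length(vocab) == 0L) abort("forum vocabulary is empty after min_count filtering")
  inc <- incidence_matrix(toks, messages$message_id, vocab, binary = TRUE)
  mat <- as.matrix(Matrix::t(inc) %*% unclass(stage1)[messages$message_id, , drop = FALSE])
  cfg <- attr(stage1, "config")
  cfg$corpus_min_count <- min_count
  vector_store(normalize_rows(mat), provenance = "corpus_terms", config = cfg)
}

#' Stage-2 message vectors: superpose corpus term vectors
#'
#' Final stage: each message's vector is the sum of the corpus-adapted
#' term vectors of its tokens (counting multiplicity), unit-normalized.
#' These are the feature vectors handed to the theme classifiers. The
#' result is a bag-of-words representation: token order never matters.
#'
#' @param corpus_terms Corpus-term `vector_store`.
#' @param messages The message tibble.
#' @param stopwords Stopword list (defaults to the store's config).
#' @return A `vector_store` with provenance `"stage2_messages"`; messages
#'   with no in-vocabulary token are flagged.
#' @export
stage2_message_vectors <- function(corpus_terms, messages, stopwords = NULL) {
  cfg <- attr(corpus_terms, "config")
  stopwords <- stopwords %||% cfg$stopwords %||% character()
  toks <- tokenize(messages$body, stopwords = stopwords,
                   drop_numeric = cfg$drop_numeric %||% FALSE)
  inc <- incidence_matrix(toks, messages$message_id, rownames(corpus_terms))
  mat <- as.matrix(inc %*% unclass(corpus_terms))
  flagged <- rownames(mat)[sqrt(rowSums(mat^2)) == 0]
  vector_store(normalize_rows(mat), provenance = "stage2_messages",
               config = attr(corpus_terms, "config"), flagged = flagged)
}

#' Run the full term/message superposition cycle
#'
#' Convenience wrapper chaining the three superposition stages:
#' background-based message vectors, corpus-adapted term vectors, and
#' final message vectors. The term/message alternation can be repeated;
#' one cycle (the default) is the canonical procedure, further iterations
#' re-derive term vectors from the latest message vectors.
#'
#' @param background Background `vector_store` from [train_background()].
#' @param messages Validated message tibble.
#' @param iterations Number of term/message cycles (default 1).
#' @param min_count Minimum forum-term frequency at the term stage.
#' @return A list with `stage1`, `corpus_terms` and `stage2` stores (the
#'   term and stage-2 entries are those of the final iteration).
#' @export
superposition_cycle <- function(background, messages, iterations = 1,
                                min_count = 5) {
  stopifnot(iterations >= 1)
  stage1 <- stage1_message_vectors(background, messages)
  msg_store <- stage1
  corpus_terms <- NULL
  for (i in seq_len(iterations)) {
    corpus_terms <- corpus_term_vectors(msg_store, messages,
                                        min_count = min_count)
    msg_store <- stage2_message_vectors(corpus_terms, messages)
  }
  list(stage1 = stage1, corpus_terms = corpus_terms, stage2 = msg_store)
}
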