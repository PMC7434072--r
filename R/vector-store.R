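#' Construct a vector store
#'
#' A vector store maps tokens or message ids to fixed-dimension real
#' vectors. It is a numeric matrix with unique rownames plus provenance
#' metadata recording which pipeline stage produced it.
#'
#' @param mat Numeric matrix; rownames are the token or message ids.
#' @param provenance One of `"background_terms"`, `"stage1_messages"`,
#'   `"corpus_terms"`, `"stage2_messages"`.
#' @param config Optional list of training/tokenizer settings (seed
#'   included) carried along for the run manifest.
#' @param flagged Character vector of ids whose vector is all-zero (e.g.
#'   messages with no in-vocabulary token).
#' @return An object of class `vector_store`.
#' @export
vector_store <- function(mat,
                         provenance = c("background_terms", "stage1_messages",
                                        "corpus_terms", "stage2_messages"),
                         config = list(), flagged = character()) {
  provenance <- match.arg(provenance)
  if (is.null(rownames(mat)) || anyDuplicated(rownames(mat)) > 0L) {
    abort("vector store rows must have unique names")
  }
  structure(mat,
            provenance = provenance, config = config, flagged = flagged,
            class = c("vector_store", "matrix", "array"))
}

#' @export
print.vector_store <- function(x, ...) {
  cat("<vector_store: ", attr(x, "provenance"), "> ", nrow(x), " x ", ncol(x),
      if (length(attr(x, "flagged"))> 0L)
        paste0(" (", length(attr(x, "flagged")), " zero-vector ids)"),
      "\n", sep = "")
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.vector_store <- function(x, ...) {
  tibble::as_tibble(unclass(x), rownames = "id")
}

#' Unit-normalize the rows of a matrix or vector store
#'
#' Rows with zero norm are left at zero. Normalization is idempotent.
#'
#' @param x Matrix or `vector_store`.
#' @return Object of the same shape with unit-Euclidean-norm rows.
#' @export
normalize_rows <- function(x) {
  nrm <- sqrt(rowSums(x^2))
  scale_ <- ifelse(nrm > 0, 1 / nrm, 0)
  out <- x * scale_
  attributes(out) <- attributes(x)
  out
}

#' Cosine similarity between stored vectors
#'
#' @param store A `vector_store`.
#' @param a,b Ids (rownames) of the two vectors, vectorized in parallel.
#' @return Numeric vector of cosines in `[-1, 1]`; 0 where either vector
#'   is all-zero.
#' @export
store_cosine <- function(store, a, b) {
  va <- store[a, , drop = FALSE]
  vb <- store[b, , drop = FALSE]
  num <- rowSums(va * vb)
  den <- sqrt(rowSums(va^2)) * sqrt(rowSums(vb^2))
  unname(ifelse(den > 0, num / den, 0))
}

#' Persist a vector store as word2vec-style text plus a JSON sidecar
#'
#' The text file holds a `"count dim"` header then one `id v1 ... vd` line
#' per vector; provenance, config and flagged ids go to `<path>.json`.
#'
#' @param store A `vector_store`.
#' @param path Output path for the text file.
#' @return `path`, invisibly.
#' @export
write_vector_store <- function(store, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(nrow(store), ncol(store)), con)
  ids <- rownames(store)
  body <- apply(unclass(store), 1L, function(v)
    paste(sprintf("%.17g", v), collapse = " "))
  writeLines(paste(ids, body), con)
  sidecar <- list(provenance = attr(store, "provenance"),
                  config = attr(store, "config"),
                  flagged = attr(store, "flagged"))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a vector store written by [write_vector_store()]
#'
#' @param path Path to the text file (its `.json` sidecar must sit beside it).
#' @return A `vector_store`.
#' @export
read_vector_store <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(lines[1], " ", fixed = TRUE)[[1]])
  parts <- strsplit(lines[-1], " ", fixed = TRUE)
  ids <- purrr::map_chr(parts, 1L)
  mat <- do.call(rbind, purrr::map(parts, ~ as.numeric(.x[-1])))
  rownames(mat) <- ids
  stopifnot(nrow(mat) == hdr[1], ncol(mat) == hdr[2])
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vector_store(mat, provenance = sidecar$provenance,
               config = as.list(sidecar$config),
               flagged = as.character(sidecar$flagged %||% character()))
}
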