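#' Read a threaded-forum message table
#'
#' Reads a message corpus from CSV or JSONL. One record per message with
#' columns `message_id`, `thread_id`, `sender_id`, `recipient_id` (empty or
#' missing when the message was posted to the forum at large), `timestamp`
#' (ISO-8601) and `body`. The result is validated: schema problems abort
#' with the offending field named; unparseable timestamps abort with the
#' offending row numbers; benign irregularities (empty bodies, missing
#' recipients) are counted and reported via attributes, never dropped.
#'
#' @param path Path to the file.
#' @param format `"csv"` or `"jsonl"`. Guessed from the extension if omitted.
#' @return A tibble of messages with a parsed `timestamp` column (POSIXct,
#'   UTC) and attribute `n_empty_body` counting empty message bodies.
#' @seealso [write_messages()], [validate_messages()]
#' @export
read_messages <- function(path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  if (!file.exists(path)) {
    abort(paste0("message file not found: ", path))
  }
  if (format == "csv") {
    raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  } else {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    raw <- purrr::map(lines, function(l) {
      tibble::as_tibble(jsonlite::fromJSON(l))
    }) |> purrr::list_rbind()
  }
  validate_messages(raw)
}

#' Validate a raw message table
#'
#' Enforces the corpus schema invariants: required fields present,
#' `message_id` unique, `thread_id` non-empty, timestamps parseable.
#'
#' @param messages Data frame with character columns as read from disk, or
#'   with an already-parsed POSIXct `timestamp`.
#' @return A validated tibble (timestamp parsed to POSIXct UTC, missing
#'   recipients as `NA`), with attribute `n_empty_body`.
#' @export
validate_messages <- function(messages) {
  required <- c("message_id", "thread_id", "sender_id", "timestamp", "body")
  missing <- setdiff(required, names(messages))
  if (length(missing) > 0L) {
    abort(paste0("message table is missing required field(s): ",
                 paste(missing, collapse = ", ")))
  }
  out <- tibble::as_tibble(messages)
  if (!"recipient_id" %in% names(out)) out$recipient_id <- NA_character_
  out <- dplyr::mutate(
    out,
    dplyr::across(c("message_id", "thread_id", "sender_id", "recipient_id", "body"),
                  as.character),
    recipient_id = dplyr::if_else(
      is.na(.data$recipient_id) | .data$recipient_id == "",
      NA_character_, .data$recipient_id
    ),
    body = dplyr::coalesce(.data$body, "")
  )

  dup <- out$message_id[duplicated(out$message_id)]
  if (length(dup) > 0L) {
    abort(paste0("duplicate message_id value(s): ",
                 paste(unique(utils::head(dup, 5L)), collapse = ", ")))
  }
  bad_thread <- which(is.na(out$thread_id) | out$thread_id == "")
  if (length(bad_thread) > 0L) {
    abort(paste0("empty thread_id at row(s): ",
                 paste(utils::head(bad_thread, 5L), collapse = ", ")))
  }
  if (inherits(out$timestamp, "POSIXct")) {
    ts <- out$timestamp
  } else {
    ts <- parse_iso8601(as.character(out$timestamp))
  }
  bad_ts <- which(is.na(ts))
  if (length(bad_ts) > 0L) {
    abort(paste0("unparseable timestamp at row(s): ",
                 paste(utils::head(bad_ts, 5L), collapse = ", ")))
  }
  out$timestamp <- ts
  n_empty <- sum(out$body == "")
  if (n_empty > 0L) {
    inform(paste0(n_empty, " message(s) have an empty body (kept)"))
  }
  out <- out[, c("message_id", "thread_id", "sender_id", "recipient_id",
                 "timestamp", "body")]
  attr(out, "n_empty_body") <- n_empty
  out
}

parse_iso8601 <- function(x) {
  ts <- as.POSIXct(x, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                  "%Y-%m-%dT%H:%M", "%Y-%m-%d"),
                   optional = TRUE)
  ts
}

#' Write a message table to CSV or JSONL
#'
#' Timestamps are serialized as ISO-8601 UTC so a read/write/read cycle is
#' field-stable (CSV) and byte-stable (JSONL).
#'
#' @param messages Validated message tibble.
#' @param path Output path.
#' @param format `"csv"` or `"jsonl"`; guessed from the extension if omitted.
#' @return `path`, invisibly.
#' @export
write_messages <- function(messages, path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  out <- dplyr::mutate(
    messages,
    timestamp = strftime(.data$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  )
  if (format == "csv") {
    readr::write_csv(out, path, na = "")
  } else {
    lines <- purrr::pmap_chr(out, function(...) {
      row <- list(...)
      row <- row[!purrr::map_lgl(row, is.na)]
      jsonlite::toJSON(row, auto_unbox = TRUE)
    })
    writeLines(lines, path, useBytes = TRUE)
  }
  invisible(path)
}

#' Read a user table
#'
#' CSV with columns `user_id`, `age`, `gender`, `quit_dates`
#' (semicolon-separated ISO dates, the historical quit-date event log,
#' possibly empty). Quit dates are returned sorted ascending in a
#' list-column of `Date` vectors.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `user_id`, `age`, `gender`, `quit_dates`.
#' @export
read_users <- function(path) {
  if (!file.exists(path)) abort(paste0("user file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  required <- c("user_id", "age", "gender", "quit_dates")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    abort(paste0("user table is missing required field(s): ",
                 paste(missing, collapse = ", ")))
  }
  validate_users(dplyr::mutate(
    raw,
    age = suppressWarnings(as.integer(.data$age)),
    quit_dates = purrr::map(.data$quit_dates, function(q) {
      if (is.na(q) || q == "") return(as.Date(character()))
      sort(as.Date(strsplit(q, ";", fixed = TRUE)[[1]]))
    })
  ))
}

validate_users <- function(users) {
  out <- tibble::as_tibble(users)
  if (anyDuplicated(out$user_id) > 0L) {
    abort("duplicate user_id in user table")
  }
  out$gender <- factor(
    dplyr::coalesce(as.character(out$gender), "other/unknown"),
    levels = c("female", "male", "other/unknown")
  )
  out$gender[is.na(out$gender)] <- "other/unknown"
  if (!is.list(out$quit_dates)) {
    abort("quit_dates must be a list-column of Date vectors")
  }
  out$quit_dates <- purrr::map(out$quit_dates, sort)
  out[, c("user_id", "age", "gender", "quit_dates")]
}

#' Write a user table to CSV
#'
#' @param users User tibble as returned by [read_users()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_users <- function(users, path) {
  out <- dplyr::mutate(
    users,
    gender = as.character(.data$gender),
    quit_dates = purrr::map_chr(.data$quit_dates, function(q) {
      paste(strftime(q, "%Y-%m-%d"), collapse = ";")
    })
  )
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Bundle messages and users into a forum corpus
#'
#' A light container used by the pipeline; most verbs in the package take
#' the message tibble directly. Senders absent from the user table are
#' auto-stubbed with unknown demographics so corpus invariants hold.
#'
#' @param messages Validated message tibble.
#' @param users Optional user tibble; stubs are created for missing senders.
#' @return An object of class `forum_corpus`: a list with `messages`,
#'   `users` and `year_range`.
#' @export
forum_corpus <- function(messages, users = NULL) {
  messages <- validate_messages(messages)
  years <- range(message_year(messages))
  senders <- unique(messages$sender_id)
  if (is.null(users)) {
    users <- tibble::tibble(user_id = character(), age = integer(),
                            gender = character(), quit_dates = list())
  }
  missing <- setdiff(senders, users$user_id)
  if (length(missing) > 0L) {
    stubs <- tibble::tibble(
      user_id = missing, age = NA_integer_,
      gender = "other/unknown",
      quit_dates = purrr::map(missing, ~ as.Date(character()))
    )
    users <- dplyr::bind_rows(dplyr::mutate(users, gender = as.character(.data$gender)), stubs)
  }
  structure(
    list(messages = messages, users = validate_users(users), year_range = years),
    class = "forum_corpus"
  )
}

#' @export
print.forum_corpus <- function(x, ...) {
  cat("<forum_corpus> ", nrow(x$messages), " messages, ",
      nrow(x$users), " users, years ", x$year_range[1], "-", x$year_range[2],
      "\n", sep = "")
  invisible(x)
}

message_year <- function(messages) {
  as.integer(format(messages$timestamp, "%Y", tz = "UTC"))
}
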