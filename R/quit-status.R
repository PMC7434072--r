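DAYS_PER_MONTH <- 30.44
DAYS_PER_YEAR <- 365.25

#' Abstinence category levels
#'
#' Six quit-duration bins plus active smoker and unknown, assigned per user
#' per year: under 3 months, 3-6 months, 6 months to 1 year, 1-2 years,
#' over 2 years, active smoker, unknown.
#'
#' @return Character vector of factor levels in stage order.
#' @export
abstinence_levels <- function() {
  c("LT_3M", "M3_TO_6M", "M6_TO_1Y", "Y1_TO_2Y", "GT_2Y",
    "ACTIVE_SMOKER", "UNKNOWN")
}

#' Parse a quit-duration signature from message text
#'
#' Community members customarily state their elapsed smoke-free time inside
#' message text ("13 days, 23 hours, 47 minutes and 51 seconds smoke free"),
#' often decorated with leading slashes. This extracts the first such
#' signature and returns the whole-day count, or `NA` when no signature is
#' present. Surrounding text never affects the parsed value.
#'
#' @param body Character vector of message bodies.
#' @return Integer vector of whole days smoke free (`NA` = no signature).
#' @examples
#' parse_quit_duration("////13 days, 23 hours, 47 minutes and 51 seconds smoke free.")
#' parse_quit_duration("400 days smoke free")
#' @export
parse_quit_duration <- function(body) {
  pat <- paste0(
    "(?i)(\\d+)\\s*days?",
    "(?:[,\\s]+(\\d+)\\s*hours?)?",
    "(?:[,\\s]+(\\d+)\\s*min(?:ute)?s?)?",
    "(?:[,\\s]+(?:and\\s+)?(\\d+)\\s*sec(?:ond)?s?)?",
    "[,\\s]*smoke[\\s-]*free"
  )
  m <- stringr::str_match(as.character(body), pat)
  as.integer(m[, 2])
}

#' Bin a quit duration into an abstinence category
#'
#' Uses fixed day constants (1 month = 30.44 days, 1 year = 365.25 days)
#' and half-open intervals `[lower, upper)` so binning is deterministic:
#' under 3 months, 3-6 months, 6 months-1 year, 1-2 years, over 2 years.
#' An active-smoker flag overrides the duration; when both inputs are
#' absent the status is unknown.
#'
#' @param days Numeric vector of days smoke free (`NA` = unknown).
#' @param is_smoking Logical vector; `TRUE` marks a self-reported active
#'   smoker.
#' @return Factor with levels [abstinence_levels()].
#' @examples
#' bin_abstinence(c(13, 400, NA))
#' @export
bin_abstinence <- function(days, is_smoking = NA) {
  n <- max(length(days), length(is_smoking))
  days <- rep_len(as.numeric(days), n)
  is_smoking <- rep_len(as.logical(is_smoking), n)
  if (any(days < 0, na.rm = TRUE)) {
    abort("negative quit durations are not valid")
  }
  cut_pts <- c(0, 3 * DAYS_PER_MONTH, 6 * DAYS_PER_MONTH,
               DAYS_PER_YEAR, 2 * DAYS_PER_YEAR, Inf)
  binned <- cut(days, breaks = cut_pts, right = FALSE,
                labels = abstinence_levels()[1:5])
  out <- as.character(binned)
  out[is.na(days)] <- "UNKNOWN"
  out[!is.na(is_smoking) & is_smoking] <- "ACTIVE_SMOKER"
  factor(out, levels = abstinence_levels())
}

#' Estimate abstinence status per user per year
#'
#' For each (user, year) in which the user posted, assigns one abstinence
#' category assessed at December 31 of the year. The quit-date event log
#' takes precedence: days = anchor minus the latest quit date on or before
#' the anchor. When no usable log entry exists, falls back to the maximum
#' quit-duration signature parsed from the user's messages that year.
#' Users with neither signal are `UNKNOWN`.
#'
#' @param messages Validated message tibble.
#' @param users Optional user tibble with a `quit_dates` list-column.
#' @return A tibble with columns `user_id`, `year`, `days`, `source`
#'   (`"log"`, `"message"` or `"none"`) and `status`.
#' @export
status_per_user_year <- function(messages, users = NULL) {
  grid <- messages |>
    dplyr::mutate(year = message_year(messages)) |>
    dplyr::distinct(user_id = .data$sender_id, .data$year)

  sig <- messages |>
    dplyr::mutate(year = message_year(messages),
                  sig_days = parse_quit_duration(.data$body)) |>
    dplyr::filter(!is.na(.data$sig_days)) |>
    dplyr::group_by(user_id = .data$sender_id, .data$year) |>
    dplyr::summarise(msg_days = max(.data$sig_days), .groups = "drop")

  out <- dplyr::left_join(grid, sig, by = c("user_id", "year"))

  if (!is.null(users)) {
    logs <- users |>
      dplyr::select("user_id", "quit_dates") |>
      dplyr::filter(purrr::map_int(.data$quit_dates, length) > 0L)
    out <- dplyr::left_join(out, logs, by = "user_id")
  } else {
    out$quit_dates <- purrr::map(seq_len(nrow(out)), ~NULL)
  }

  out |>
    dplyr::mutate(
      anchor = as.Date(paste0(.data$year, "-12-31")),
      log_days = purrr::map2_dbl(.data$quit_dates, .data$anchor, function(q, a) {
        if (is.null(q) || length(q) == 0L) return(NA_real_)
        q <- q[q <= a]
        if (length(q) == 0L) return(NA_real_)
        as.numeric(a - max(q))
      }),
      days = dplyr::coalesce(.data$log_days, as.numeric(.data$msg_days)),
      source = dplyr::case_when(
        !is.na(.data$log_days) ~ "log",
        !is.na(.data$msg_days) ~ "message",
        TRUE ~ "none"
      ),
      status = bin_abstinence(.data$days)
    ) |>
    dplyr::select("user_id", "year", "days", "source", "status")
}
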