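ENGAGEMENT_GROUPS <- c(INITIATOR = "threads_initiated",
                       ATTRACTOR = "replies_attracted",
                       FREQUENT_POSTER = "posts")

#' Compute per-user per-year engagement profiles
#'
#' Three count-based frequency metrics per calendar year:
#' * `threads_initiated` — threads whose earliest message (ties broken by
#'   message id) was sent by the user, attributed to the root's year;
#' * `posts` — all messages the user sent that year;
#' * `replies_attracted` — messages addressed to the user via
#'   `recipient_id`, or posted without an explicit recipient into a thread
#'   the user rooted, excluding the user's own messages, attributed to the
#'   reply's year.
#'
#' @param messages Validated message tibble.
#' @return A tibble with columns `user_id`, `year`, `threads_initiated`,
#'   `posts`, `replies_attracted`; one row per (user, year) with any
#'   activity.
#' @export
compute_profiles <- function(messages) {
  msg <- messages |>
    dplyr::mutate(year = message_year(messages))

  roots <- msg |>
    dplyr::arrange(.data$timestamp, .data$message_id) |>
    dplyr::distinct(.data$thread_id, .keep_all = TRUE) |>
    dplyr::select("thread_id", root_sender = "sender_id",
                  root_message = "message_id", root_year = "year")

  threads <- roots |>
    dplyr::count(user_id = .data$root_sender, year = .data$root_year,
                 name = "threads_initiated")

  posts <- msg |>
    dplyr::count(user_id = .data$sender_id, .data$year, name = "posts")

  replies <- msg |>
    dplyr::left_join(roots, by = "thread_id") |>
    dplyr::mutate(target = dplyr::coalesce(.data$recipient_id, .data$root_sender)) |>
    dplyr::filter(.data$target != .data$sender_id) |>
    dplyr::count(user_id = .data$target, .data$year, name = "replies_attracted")

  posts |>
    dplyr::full_join(threads, by = c("user_id", "year")) |>
    dplyr::full_join(replies, by = c("user_id", "year")) |>
    dplyr::mutate(dplyr::across(c("threads_initiated", "posts", "replies_attracted"),
                                ~ dplyr::coalesce(.x, 0L))) |>
    dplyr::select("user_id", "year", "threads_initiated", "posts",
                  "replies_attracted") |>
    dplyr::arrange(.data$user_id, .data$year)
}

#' Select the top-k users per year on one engagement metric
#'
#' Per year, the `k` highest-ranked users by the metric among users with a
#' non-zero metric value. Ties are broken deterministically by higher
#' `posts`, then lexicographic `user_id`, so the selection is invariant to
#' input ordering. Years with fewer than `k` active users return all of
#' them with a warning.
#'
#' @param profiles Profile tibble from [compute_profiles()].
#' @param metric One of `"threads_initiated"`, `"posts"`,
#'   `"replies_attracted"`.
#' @param k Number of users per year (default 3).
#' @param years Integer vector of years to cover (default: all years in
#'   `profiles`).
#' @return A tibble with columns `group`, `year`, `rank`, `user_id`,
#'   `metric`, `value`.
#' @export
select_top_users <- function(profiles,
                             metric = c("threads_initiated", "posts",
                                        "replies_attracted"),
                             k = 3, years = NULL) {
  metric <- match.arg(metric)
  stopifnot(k >= 1)
  years <- years %||% sort(unique(profiles$year))
  group <- names(ENGAGEMENT_GROUPS)[ENGAGEMENT_GROUPS == metric]

  out <- purrr::map(years, function(y) {
    active <- profiles |>
      dplyr::filter(.data$year == y, .data[[metric]] > 0) |>
      dplyr::arrange(dplyr::desc(.data[[metric]]), dplyr::desc(.data$posts),
                     .data$user_id)
    if (nrow(active) < k) {
      warn(paste0("year ", y, ": only ", nrow(active),
                  " active user(s) for metric ", metric, " (k = ", k, ")"))
    }
    sel <- utils::head(active, k)
    values <- sel[[metric]]
    tibble::tibble(group = group, year = y,
                   rank = seq_len(nrow(sel)),
                   user_id = sel$user_id, metric = metric,
                   value = values)
  }) |> purrr::list_rbind()
  out
}

#' Assign top-k engagement groups for all three metrics
#'
#' Convenience wrapper running [select_top_users()] for conversation
#' initiators (threads initiated), conversation attractors (replies
#' attracted) and frequent posters (messages posted). A user may hold
#' multiple memberships in a year.
#'
#' @inheritParams select_top_users
#' @return A tibble of assignments across the three groups.
#' @export
engagement_groups <- function(profiles, k = 3, years = NULL) {
  purrr::map(unname(ENGAGEMENT_GROUPS),
             ~ select_top_users(profiles, .x, k = k, years = years)) |>
    purrr::list_rbind()
}

#' Round-half-up percentage
#'
#' Shared rounding rule for every reported share: `100 * numerator /
#' denominator`, rounded half-up at the requested number of decimals.
#'
#' @param numerator,denominator Non-negative counts, `numerator <=
#'   denominator`, `denominator > 0`.
#' @param decimals Decimal places to keep (default 2).
#' @return Numeric percentage.
#' @examples
#' proportion(19056, 26466)   # 72.00
#' proportion(119, 144, 1)    # 82.6
#' @export
proportion <- function(numerator, denominator, decimals = 2) {
  if (any(denominator <= 0)) abort("denominator must be positive")
  if (any(numerator < 0 | numerator > denominator)) {
    abort("numerator must lie in [0, denominator]")
  }
  p <- 100 * numerator / denominator
  scale <- 10^decimals
  floor(p * scale + 0.5 + 1e-9) / scale
}

#' Summarise demographics and abstinence status per engagement group
#'
#' Percentages are computed over the group's distinct (user, year) slots:
#' a user selected in several years contributes one slot per year, matching
#' the slot-based denominators of the selection step.
#'
#' @param assignments Assignment tibble from [engagement_groups()].
#' @param users User tibble (age, gender).
#' @param statuses Status tibble from [status_per_user_year()].
#' @param decimals Decimal places for percentages.
#' @return An object of class `group_summary`: a list of tidy tibbles
#'   `gender`, `age` and `status`, plus slot counts.
#' @export
group_summary <- function(assignments, users, statuses, decimals = 1) {
  if (nrow(assignments) == 0L) abort("no assignments to summarise")
  slots <- assignments |>
    dplyr::distinct(.data$group, .data$user_id, .data$year) |>
    dplyr::left_join(dplyr::select(users, "user_id", "age", "gender"),
                     by = "user_id") |>
    dplyr::left_join(dplyr::select(statuses, "user_id", "year", "status"),
                     by = c("user_id", "year")) |>
    dplyr::mutate(
      gender = factor(dplyr::coalesce(as.character(.data$gender), "other/unknown"),
                      levels = c("female", "male", "other/unknown")),
      status = factor(dplyr::coalesce(as.character(.data$status), "UNKNOWN"),
                      levels = abstinence_levels())
    )

  denom <- slots |> dplyr::count(.data$group, name = "n_slots")

  gender <- slots |>
    dplyr::count(.data$group, .data$gender, .drop = FALSE, name = "n") |>
    dplyr::left_join(denom, by = "group") |>
    dplyr::mutate(pct = proportion(.data$n, .data$n_slots, decimals))

  age <- slots |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(mean_age = mean(.data$age, na.rm = TRUE),
                     sd_age = stats::sd(.data$age, na.rm = TRUE),
                     n_known = sum(!is.na(.data$age)), .groups = "drop")

  status <- slots |>
    dplyr::count(.data$group, .data$status, .drop = FALSE, name = "n") |>
    dplyr::left_join(denom, by = "group") |>
    dplyr::mutate(pct = proportion(.data$n, .data$n_slots, decimals))

  structure(list(gender = gender, age = age, status = status,
                 slots = denom, decimals = decimals),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat("<group_summary> over",
      sum(x$slots$n_slots), "slots in", nrow(x$slots), "groups\n")
  print(x$gender)
  print(x$age)
  invisible(x)
}

#' @describeIn group_summary Tidy a group summary into one long tibble with
#'   columns `group`, `measure`, `category`, `n`, `n_slots`, `pct`.
#' @param x A `group_summary` object.
#' @param ... Unused.
#' @export
tidy.group_summary <- function(x, ...) {
  dplyr::bind_rows(
    x$gender |>
      dplyr::mutate(measure = "gender", category = as.character(.data$gender)) |>
      dplyr::select("group", "measure", "category", "n", "n_slots", "pct"),
    x$status |>
      dplyr::mutate(measure = "abstinence", category = as.character(.data$status)) |>
      dplyr::select("group", "measure", "category", "n", "n_slots", "pct")
  )
}
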