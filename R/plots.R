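#' Plot per-group theme prevalence
#'
#' Bar panel per engagement group showing the share of the group's
#' messages carrying each retained theme (multi-label: shares need not
#' sum to 100).
#'
#' @param prevalence Tibble from [theme_prevalence_by_group()].
#' @return A ggplot object.
#' @export
plot_theme_prevalence <- function(prevalence) {
  ggplot2::ggplot(prevalence,
                  ggplot2::aes(x = .data$pct,
                               y = stats::reorder(.data$theme, .data$pct))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "% of group messages", y = NULL,
                  title = "Theme prevalence by engagement group")
}

#' Plot per-group sentiment shares
#'
#' Stacked positive/negative/neutral shares of each group's messages.
#'
#' @param shares Tibble from [sentiment_by_group()].
#' @return A ggplot object.
#' @export
plot_sentiment_shares <- function(shares) {
  ggplot2::ggplot(shares,
                  ggplot2::aes(x = .data$group, y = .data$pct,
                               fill = .data$direction)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_manual(values = c(positive = "#2c7fb8",
                                          negative = "#d95f0e",
                                          neutral = "grey70")) +
    ggplot2::labs(x = NULL, y = "% of group messages", fill = "direction",
                  title = "Sentiment direction by engagement group")
}

#' Plot abstinence-status composition per group
#'
#' @param summary A `group_summary` object.
#' @return A ggplot object.
#' @export
plot_group_status <- function(summary) {
  ggplot2::ggplot(summary$status,
                  ggplot2::aes(x = .data$group, y = .data$pct,
                               fill = .data$status)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "% of group slots", fill = "abstinence",
                  title = "Abstinence status by engagement group")
}

#' @describeIn cv_themes Autoplot method: per-theme precision, recall and
#'   F-measure for retained themes.
#' @param object A `theme_cv_report`.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.theme_cv_report <- function(object, ...) {
  dat <- tibble::as_tibble(object) |>
    dplyr::filter(.data$retained) |>
    tidyr::pivot_longer(c("precision", "recall", "f_measure"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$value, y = .data$theme,
                                    colour = .data$metric)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "cross-validated score", y = NULL,
                  title = "Per-theme classifier performance")
}
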