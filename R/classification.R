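#' The 16-category behavior change technique taxonomy
#'
#' Thematic category slugs used for message coding: the 16 high-level
#' clusters of the behavior change technique taxonomy (goals and planning,
#' feedback and monitoring, social support, ...). Any other character
#' vector of theme names may be supplied wherever a taxonomy is expected.
#'
#' @return Character vector of 16 theme slugs.
#' @export
bct_taxonomy <- function() {
  c("goals_and_planning", "feedback_and_monitoring", "social_support",
    "shaping_knowledge", "natural_consequences", "comparison_of_behavior",
    "associations", "repetition_and_substitution", "comparison_of_outcomes",
    "rewards_and_threat", "regulation", "antecedents", "identity",
    "scheduled_consequences", "self_belief", "covert_learning")
}

#' Read message theme annotations
#'
#' CSV with columns `message_id` and `themes` (pipe-separated theme slugs;
#' empty = annotated as carrying no theme). Returned long: one row per
#' (message, theme); messages annotated with no theme keep one row with
#' `theme = NA` so the annotated set is preserved.
#'
#' @param path Path to the annotations CSV.
#' @return Long tibble with columns `message_id`, `theme`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) abort(paste0("annotations file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("message_id", "themes") %in% names(raw))) {
    abort("annotations table must have columns message_id, themes")
  }
  raw |>
    dplyr::mutate(theme = purrr::map(.data$themes, function(t) {
      if (is.na(t) || t == "") NA_character_
      else strsplit(t, "|", fixed = TRUE)[[1]]
    })) |>
    tidyr::unnest("theme") |>
    dplyr::select("message_id", "theme")
}

#' Write long annotations back to the pipe-separated CSV form
#'
#' @param annotations Long annotation tibble (`message_id`, `theme`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  annotations |>
    dplyr::group_by(.data$message_id) |>
    dplyr::summarise(
      themes = paste(sort(.data$theme[!is.na(.data$theme)]), collapse = "|"),
      .groups = "drop") |>
    readr::write_csv(path, na = "")
  invisible(path)
}

#' Filter themes by positive-example support
#'
#' Themes without enough positive training examples cannot support a
#' cross-validated classifier and are dropped from automated labeling.
#' The report lists every taxonomy theme with its positive count and
#' whether it was retained.
#'
#' @param annotations Long annotation tibble.
#' @param taxonomy Character vector of candidate themes
#'   (default [bct_taxonomy()]).
#' @param min_positives Minimum positive examples to retain a theme
#'   (default 30, a defensible floor for 10-fold stratification).
#' @return A tibble with columns `theme`, `n_positive`, `retained`.
#' @export
filter_themes <- function(annotations, taxonomy = bct_taxonomy(),
                          min_positives = 30) {
  if (nrow(annotations) == 0L) abort("annotations are empty")
  counts <- annotations |>
    dplyr::filter(!is.na(.data$theme)) |>
    dplyr::count(.data$theme, name = "n_positive")
  out <- tibble::tibble(theme = taxonomy) |>
    dplyr::left_join(counts, by = "theme") |>
    dplyr::mutate(n_positive = dplyr::coalesce(.data$n_positive, 0L),
                  retained = .data$n_positive >= min_positives)
  if (!any(out$retained)) {
    abort("no theme meets the min_positives threshold")
  }
  out
}

theme_training_frame <- function(features, annotations, theme) {
  ann_ids <- unique(annotations$message_id)
  missing <- setdiff(ann_ids, rownames(features))
  if (length(missing) > 0L) {
    abort(paste0("annotated message(s) missing from feature store: ",
                 paste(utils::head(missing, 3L), collapse = ", ")))
  }
  pos_ids <- annotations$message_id[!is.na(annotations$theme) &
                                      annotations$theme == theme]
  x <- unclass(features)[ann_ids, , drop = FALSE]
  y <- factor(ifelse(ann_ids %in% pos_ids, "pos", "neg"),
              levels = c("neg", "pos"))
  list(ids = ann_ids, x = x, y = y)
}

discretize_columns <- function(x, breaks) {
  out <- as.data.frame(x)
  for (j in seq_along(out)) {
    out[[j]] <- cut(out[[j]], breaks = breaks[[j]], include.lowest = TRUE)
  }
  out
}

#' Train a per-theme binary naive Bayes classifier
#'
#' Binary probabilistic classifier for one theme over stage-2 message
#' vectors. The default event model is Gaussian (continuous embedding
#' components); a discretized multinomial alternative (equal-frequency
#' bins per component) is available. Decision threshold is 0.5 on the
#' positive-class posterior.
#'
#' @param features Stage-2 `vector_store` (or numeric matrix with message
#'   ids as rownames).
#' @param annotations Long annotation tibble defining the training set:
#'   every annotated message is an example, positive when tagged with
#'   `theme`.
#' @param theme Theme slug to train on.
#' @param event_model `"gaussian"` (default) or `"multinomial"`.
#' @param bins Bin count per component for the discretized model.
#' @return An object of class `theme_classifier`.
#' @export
train_theme_classifier <- function(features, annotations, theme,
                                   event_model = c("gaussian", "multinomial"),
                                   bins = 4) {
  event_model <- match.arg(event_model)
  tf <- theme_training_frame(features, annotations, theme)
  if (nlevels(droplevels(tf$y)) < 2L) {
    abort(paste0("training set for theme '", theme, "' has a single class"))
  }
  breaks <- NULL
  if (event_model == "multinomial") {
    breaks <- purrr::map(seq_len(ncol(tf$x)), function(j) {
      b <- unique(stats::quantile(tf$x[, j], probs = seq(0, 1, length.out = bins + 1)))
      if (length(b) < 2L) b <- c(b - 1e-8, b + 1e-8)
      b[1] <- -Inf; b[length(b)] <- Inf
      b
    })
    x <- discretize_columns(tf$x, breaks)
  } else {
    x <- as.data.frame(tf$x)
  }
  model <- e1071::naiveBayes(x, tf$y)
  structure(list(model = model, theme = theme, event_model = event_model,
                 breaks = breaks, threshold = 0.5,
                 dimension = ncol(tf$x), n_positive = sum(tf$y == "pos")),
            class = "theme_classifier")
}

#' @export
print.theme_classifier <- function(x, ...) {
  cat("<theme_classifier> theme:", x$theme, "| event model:", x$event_model,
      "| positives:", x$n_positive, "\n")
  invisible(x)
}

#' Predict theme membership for messages
#'
#' @param object A `theme_classifier`.
#' @param features `vector_store` or matrix of message vectors.
#' @param ... Unused.
#' @return Tibble with columns `message_id`, `prob` (positive-class
#'   posterior), `label` (posterior >= 0.5).
#' @export
predict.theme_classifier <- function(object, features, ...) {
  x <- unclass(features)
  if (object$event_model == "multinomial") {
    x <- discretize_columns(x, object$breaks)
  } else {
    x <- as.data.frame(x)
  }
  prob <- predict(object$model, x, type = "raw")[, "pos"]
  tibble::tibble(message_id = rownames(features), prob = unname(prob),
                 label = unname(prob) >= object$threshold)
}

#' Stratified k-fold cross-validation for one theme classifier
#'
#' Fold assignment is stratified by class and driven by the seed, so the
#' report is invariant to message order. Metrics are pooled (micro) over
#' the held-out folds by default — precision, recall and F-measure
#' recomputed from the single summed confusion matrix — with per-fold
#' averaging available. When a class has fewer members than `folds`, the
#' fold count is reduced automatically with a warning.
#'
#' @inheritParams train_theme_classifier
#' @param folds Number of folds (default 10).
#' @param seed Integer seed for fold assignment.
#' @param averaging `"pooled"` (default) or `"per_fold"`.
#' @return One-row tibble of class `theme_report`: `theme`, `n_positive`,
#'   `precision`, `recall`, `f_measure`, `folds`, plus a `confusion`
#'   attribute (tp, fp, fn, tn).
#' @export
cross_validate <- function(features, annotations, theme, folds = 10, seed = 1,
                           event_model = c("gaussian", "multinomial"),
                           averaging = c("pooled", "per_fold")) {
  event_model <- match.arg(event_model)
  averaging <- match.arg(averaging)
  stopifnot(folds >= 2)
  tf <- theme_training_frame(features, annotations, theme)
  n_pos <- sum(tf$y == "pos"); n_neg <- sum(tf$y == "neg")
  if (n_pos == 0L || n_neg == 0L) {
    abort(paste0("cannot cross-validate single-class theme '", theme, "'"))
  }
  k <- min(folds, n_pos, n_neg)
  if (k < folds) {
    warn(paste0("theme '", theme, "': reducing folds from ", folds, " to ", k,
                " (smallest class has ", min(n_pos, n_neg), " examples)"))
  }
  # deterministic stratified fold assignment, independent of input order
  fold_of <- integer(length(tf$ids))
  for (cls in c("pos", "neg")) {
    idx <- which(tf$y == cls)
    idx <- idx[order(tf$ids[idx])]
    sh <- withr::with_seed(seed, sample(idx))
    fold_of[sh] <- rep_len(seq_len(k), length(sh))
  }

  fold_stats <- purrr::map(seq_len(k), function(f) {
    test <- fold_of == f
    ann_train <- tibble::tibble(
      message_id = tf$ids[!test],
      theme = ifelse(tf$y[!test] == "pos", theme, NA_character_))
    clf <- train_theme_classifier(unclass(features)[tf$ids[!test], , drop = FALSE],
                                  ann_train, theme, event_model = event_model)
    pred <- predict(clf, unclass(features)[tf$ids[test], , drop = FALSE])
    truth <- tf$y[test] == "pos"
    tibble::tibble(
      tp = sum(pred$label & truth), fp = sum(pred$label & !truth),
      fn = sum(!pred$label & truth), tn = sum(!pred$label & !truth))
  }) |> purrr::list_rbind()

  conf <- dplyr::summarise(fold_stats, dplyr::across(dplyr::everything(), sum))
  if (averaging == "pooled") {
    m <- prf_from_confusion(conf$tp, conf$fp, conf$fn)
  } else {
    per <- purrr::pmap(fold_stats, function(tp, fp, fn, tn) {
      prf_from_confusion(tp, fp, fn)
    }) |> purrr::list_rbind()
    m <- dplyr::summarise(per, dplyr::across(dplyr::everything(), mean))
  }
  out <- tibble::tibble(theme = theme, n_positive = n_pos,
                        precision = m$precision, recall = m$recall,
                        f_measure = m$f_measure, folds = k)
  attr(out, "confusion") <- conf
  class(out) <- c("theme_report", class(out))
  out
}

prf_from_confusion <- function(tp, fp, fn) {
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  tibble::tibble(precision = precision, recall = recall, f_measure = f)
}

#' Cross-validate every retained theme
#'
#' @inheritParams cross_validate
#' @param theme_filter Output of [filter_themes()]; only retained themes
#'   are cross-validated, but all appear in the report.
#' @return A tibble of class `theme_cv_report`: one row per taxonomy theme
#'   with `n_positive`, `retained` and (for retained themes) pooled
#'   `precision`, `recall`, `f_measure`; summed confusion in the
#'   `confusion` attribute.
#' @export
cv_themes <- function(features, annotations, theme_filter, folds = 10,
                      seed = 1, event_model = c("gaussian", "multinomial")) {
  event_model <- match.arg(event_model)
  reports <- purrr::map(theme_filter$theme[theme_filter$retained],
                        function(th) {
    cross_validate(features, annotations, th, folds = folds, seed = seed,
                   event_model = event_model)
  })
  conf <- purrr::map(reports, attr, "confusion") |>
    purrr::list_rbind() |>
    dplyr::summarise(dplyr::across(dplyr::everything(), sum))
  out <- theme_filter |>
    dplyr::left_join(purrr::list_rbind(purrr::map(reports, tibble::as_tibble)),
                     by = c("theme", "n_positive")) |>
    dplyr::select("theme", "n_positive", "retained", "precision", "recall",
                  "f_measure", "folds")
  attr(out, "confusion") <- conf
  class(out) <- c("theme_cv_report", class(out))
  out
}

#' @describeIn cv_themes Tidy method: the per-theme report rows.
#' @param x A `theme_cv_report`.
#' @param ... Unused.
#' @export
tidy.theme_cv_report <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @describeIn cv_themes Glance method: one row with macro-averaged and
#'   pooled-across-themes precision/recall/F over retained themes.
#' @export
glance.theme_cv_report <- function(x, ...) {
  kept <- dplyr::filter(tibble::as_tibble(x), .data$retained)
  conf <- attr(x, "confusion")
  pooled <- prf_from_confusion(conf$tp, conf$fp, conf$fn)
  tibble::tibble(
    n_themes = nrow(x), n_retained = nrow(kept),
    macro_precision = mean(kept$precision), macro_recall = mean(kept$recall),
    macro_f = mean(kept$f_measure),
    pooled_precision = pooled$precision, pooled_recall = pooled$recall,
    pooled_f = pooled$f_measure)
}

#' Label an entire corpus with every retained theme
#'
#' Independent binary decision per theme per message: one theme's
#' classifier never affects another's labels. Messages flagged as
#' zero-vector in the feature store receive no labels.
#'
#' @param classifiers Named list of `theme_classifier` objects.
#' @param features Stage-2 `vector_store`.
#' @return Long tibble `message_id`, `theme` with one row per assigned
#'   label (messages with no label are absent).
#' @export
label_corpus <- function(classifiers, features) {
  if (length(classifiers) == 0L || nrow(features) == 0L) {
    return(tibble::tibble(message_id = character(), theme = character()))
  }
  flagged <- attr(features, "flagged") %||% character()
  keep <- setdiff(rownames(features), flagged)
  x <- unclass(features)[keep, , drop = FALSE]
  purrr::map(classifiers, function(clf) {
    pred <- predict(clf, x)
    tibble::tibble(message_id = pred$message_id[pred$label], theme = clf$theme)
  }) |>
    purrr::list_rbind() |>
    dplyr::arrange(.data$message_id, .data$theme)
}

#' Theme prevalence per engagement group
#'
#' For each group, the share of its messages carrying each theme. The
#' denominator is every message sent by the group's selected (user, year)
#' slots during their selected years; rows are unconstrained multi-label
#' shares in `[0, 100]`.
#'
#' @param labels Long label tibble from [label_corpus()].
#' @param assignments Group assignments from [engagement_groups()].
#' @param messages The message tibble.
#' @param themes Themes to tabulate (default: those present in `labels`).
#' @param decimals Decimal places for percentages.
#' @return Tibble `group`, `theme`, `n`, `denominator`, `pct`.
#' @export
theme_prevalence_by_group <- function(labels, assignments, messages,
                                      themes = NULL, decimals = 2) {
  themes <- themes %||% sort(unique(labels$theme))
  gm <- group_messages(assignments, messages)
  if (nrow(gm) == 0L) {
    warn("no group has any message; empty prevalence table")
    return(tibble::tibble(group = character(), theme = character(),
                          n = integer(), denominator = integer(),
                          pct = numeric()))
  }
  denom <- gm |> dplyr::count(.data$group, name = "denominator")
  gm |>
    dplyr::inner_join(labels, by = "message_id",
                      relationship = "many-to-many") |>
    dplyr::count(.data$group, .data$theme, name = "n") |>
    tidyr::complete(group = unique(gm$group), theme = themes,
                    fill = list(n = 0L)) |>
    dplyr::filter(.data$theme %in% themes) |>
    dplyr::left_join(denom, by = "group") |>
    dplyr::mutate(pct = proportion(.data$n, .data$denominator, decimals)) |>
    dplyr::arrange(.data$group, .data$theme)
}

# messages attributed to each group's selected (user, year) slots
group_messages <- function(assignments, messages) {
  msg <- dplyr::mutate(messages, year = message_year(messages))
  assignments |>
    dplyr::distinct(.data$group, .data$user_id, .data$year) |>
    dplyr::inner_join(msg, by = c(user_id = "sender_id", year = "year"),
                      relationship = "many-to-many") |>
    dplyr::select("group", "message_id", "user_id", "year")
}

#' Cohen's kappa for two label sequences
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` between two
#' equal-length categorical sequences, used both for system-rater
#' agreement and inter-coder reliability.
#'
#' @param labels_a,labels_b Equal-length vectors (coerced to character).
#' @return Kappa as a single number; 1 when both observed and expected
#'   agreement are perfect.
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    abort("label sequences must have equal length")
  }
  a <- as.character(labels_a); b <- as.character(labels_b)
  levels_ <- union(a, b)
  a <- factor(a, levels = levels_); b <- factor(b, levels = levels_)
  po <- mean(a == b)
  pe <- sum(prop.table(table(a)) * prop.table(table(b)))
  if (abs(1 - pe) < .Machine$double.eps^0.5) {
    return(if (po >= 1 - .Machine$double.eps^0.5) 1 else 0)
  }
  (po - pe) / (1 - pe)
}
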