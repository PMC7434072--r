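# helper: linearly separated two-class feature fixture
separable_features <- function(n_pos = 30, n_neg = 50, dim = 6, gap = 4,
                               seed = 21) {
  withr::with_seed(seed, {
    x <- rbind(matrix(stats::rnorm(n_pos * dim, gap), n_pos, dim),
               matrix(stats::rnorm(n_neg * dim, -gap), n_neg, dim))
    rownames(x) <- sprintf("m%03d", seq_len(n_pos + n_neg))
    ann <- tibble::tibble(
      message_id = rownames(x),
      theme = c(rep("goals_and_planning", n_pos), rep(NA_character_, n_neg)))
    list(x = x, ann = ann)
  })
}

test_that("theme filtering tallies positives and retains by threshold", {
  fx <- study_fixture()
  tf <- filter_themes(fx$annotations, min_positives = 30)
  brute <- table(fx$annotations$theme[!is.na(fx$annotations$theme)])
  for (th in tf$theme) {
    want <- if (th %in% names(brute)) as.integer(brute[[th]]) else 0L
    expect_equal(tf$n_positive[tf$theme == th], want)
  }
  expect_identical(tf$theme[tf$retained],
                   tf$theme[tf$n_positive >= 30])
  all16 <- filter_themes(fx$annotations, min_positives = 0)
  expect_true(all(all16$retained))
  expect_equal(nrow(all16), 16)
  expect_error(filter_themes(fx$annotations, min_positives = 1e6),
               "no theme")
})

test_that("a separable fixture trains to perfect accuracy and perfect CV metrics", {
  sep <- separable_features()
  clf <- train_theme_classifier(sep$x, sep$ann, "goals_and_planning")
  pred <- predict(clf, sep$x)
  truth <- !is.na(sep$ann$theme)
  expect_equal(pred$label, truth)
  rep <- cross_validate(sep$x, sep$ann, "goals_and_planning",
                        folds = 10, seed = 4)
  expect_equal(rep$precision, 1)
  expect_equal(rep$recall, 1)
  expect_equal(rep$f_measure, 1)
  # single-class training set errors, naming the theme
  neg_only <- dplyr::mutate(sep$ann, theme = NA_character_)
  expect_error(train_theme_classifier(sep$x, neg_only, "goals_and_planning"),
               "goals_and_planning")
})

test_that("pooled metrics reproduce exactly from the summed confusion matrix", {
  sep <- separable_features(gap = 0.4, seed = 22)  # overlapping classes
  rep <- cross_validate(sep$x, sep$ann, "goals_and_planning",
                        folds = 10, seed = 4)
  conf <- attr(rep, "confusion")
  expect_equal(conf$tp + conf$fp + conf$fn + conf$tn, nrow(sep$x))
  p <- conf$tp / (conf$tp + conf$fp)
  r <- conf$tp / (conf$tp + conf$fn)
  expect_equal(rep$precision, p)
  expect_equal(rep$recall, r)
  expect_equal(rep$f_measure, 2 * p * r / (p + r))
})

test_that("cross-validation reports are invariant to input order at fixed seed", {
  sep <- separable_features(gap = 0.6, seed = 23)
  rep1 <- cross_validate(sep$x, sep$ann, "goals_and_planning",
                         folds = 5, seed = 8)
  perm <- withr::with_seed(1, sample(nrow(sep$x)))
  rep2 <- cross_validate(sep$x[perm, ], sep$ann[perm, ], "goals_and_planning",
                         folds = 5, seed = 8)
  expect_equal(as.data.frame(rep1), as.data.frame(rep2))
})

test_that("scarce positives trigger automatic fold reduction with a warning", {
  sep <- separable_features(n_pos = 6, n_neg = 40, seed = 24)
  expect_warning(
    rep <- cross_validate(sep$x, sep$ann, "goals_and_planning",
                          folds = 10, seed = 2),
    "reducing folds")
  expect_equal(rep$folds, 6)
})

test_that("label permutation drives CV performance to the base rate", {
  fx <- study_fixture()
  s2 <- fixture_stores()$stage2
  theme <- "goals_and_planning"
  ann <- fx$annotations
  ids <- unique(ann$message_id)
  is_pos <- ids %in% ann$message_id[!is.na(ann$theme) & ann$theme == theme]
  base_rate <- mean(is_pos)
  perm <- withr::with_seed(99, sample(is_pos))
  ann_perm <- tibble::tibble(
    message_id = ids,
    theme = ifelse(perm, theme, NA_character_))
  rep_perm <- cross_validate(s2, ann_perm, theme, folds = 10, seed = 4)
  rep_true <- cross_validate(s2, ann, theme, folds = 10, seed = 4)
  expect_lt(rep_perm$f_measure, base_rate + 0.15)
  expect_gt(rep_true$f_measure, rep_perm$f_measure + 0.3)
})

test_that("corpus labeling is empty-safe, skips flagged messages and is per-theme independent", {
  expect_equal(nrow(label_corpus(list(), fixture_stores()$stage2)), 0)

  sep <- separable_features(seed = 25)
  clf <- train_theme_classifier(sep$x, sep$ann, "goals_and_planning")
  feats <- vector_store(sep$x, provenance = "stage2_messages",
                        flagged = rownames(sep$x)[1:3])
  labels <- label_corpus(list(goals_and_planning = clf), feats)
  expect_false(any(rownames(sep$x)[1:3] %in% labels$message_id))

  # adding a second theme's classifier never changes the first theme's labels
  ann2 <- sep$ann
  ann2$theme[40:60] <- "social_support"
  clf2 <- train_theme_classifier(sep$x, ann2, "social_support")
  both <- label_corpus(list(goals_and_planning = clf, social_support = clf2),
                       feats)
  expect_identical(both$message_id[both$theme == "goals_and_planning"],
                   labels$message_id)
})

test_that("models relabel their own training set consistently", {
  fx <- study_fixture()
  s2 <- fixture_stores()$stage2
  tf <- filter_themes(fx$annotations)
  themes <- tf$theme[tf$retained]
  clfs <- purrr::map(setNames(themes, themes),
                     ~ train_theme_classifier(s2, fx$annotations, .x))
  ids <- unique(fx$annotations$message_id)
  sub <- vector_store(unclass(s2)[ids, ], provenance = "stage2_messages")
  labels <- label_corpus(clfs, sub)
  truth <- dplyr::filter(fx$annotations, !is.na(theme), theme %in% themes)
  key <- function(d) paste(d$message_id, d$theme)
  jaccard <- length(intersect(key(labels), key(truth))) /
    length(union(key(labels), key(truth)))
  expect_gte(jaccard, 0.9)
  # per-decision resubstitution agreement over annotated x retained pairs
  all_pairs <- paste(rep(ids, each = length(themes)), themes)
  agree <- mean((all_pairs %in% key(labels)) == (all_pairs %in% key(truth)))
  expect_gte(agree, 0.95)
})

test_that("labeled theme prevalence tracks the generator mixture within 5 points", {
  fx <- study_fixture()
  s2 <- fixture_stores()$stage2
  tf <- filter_themes(fx$annotations)
  themes <- tf$theme[tf$retained]
  clfs <- purrr::map(setNames(themes, themes),
                     ~ train_theme_classifier(s2, fx$annotations, .x))
  labels <- label_corpus(clfs, s2)
  n <- nrow(fx$messages)
  truth_long <- fx$truth$message_truth |>
    dplyr::select("message_id", "themes") |>
    tidyr::unnest("themes")
  for (th in themes) {
    true_pct <- 100 * sum(truth_long$themes == th) / n
    lab_pct <- 100 * sum(labels$theme == th) / n
    expect_lt(abs(lab_pct - true_pct), 5)
  }
})

test_that("per-group theme prevalence uses slot-message denominators", {
  labels <- tibble::tibble(message_id = c("m1", "m2"),
                           theme = "social_support")
  msgs <- make_messages(c("m1", "m2", "m3"), "t1", c("A", "A", "B"))
  asg <- tibble::tibble(group = "INITIATOR", year = 2014L, rank = 1L,
                        user_id = "A", metric = "threads_initiated",
                        value = 1L)
  prev <- theme_prevalence_by_group(labels, asg, msgs,
                                    themes = c("social_support",
                                               "self_belief"))
  expect_equal(prev$denominator, c(2L, 2L))
  expect_equal(prev$pct[prev$theme == "social_support"], 100)
  expect_equal(prev$pct[prev$theme == "self_belief"], 0)
})

test_that("Cohen's kappa matches the closed form and its edge cases", {
  expect_equal(cohen_kappa(c("a", "b", "c"), c("a", "b", "c")), 1)
  expect_error(cohen_kappa(1:3, 1:4), "equal length")

  # hand-computed 3x3 confusion table:
  # diag (20, 30, 10); A1B2 = 5, A2B1 = 5, A2B3 = 5, A3B2 = 5; n = 80
  # po = 60/80; marginals both (25, 40, 15)/80 ->
  # pe = (25^2 + 40^2 + 15^2)/80^2 = 2450/6400
  # kappa = (0.75 - 0.3828125)/(1 - 0.3828125) = 0.5949367...
  a <- rep(c("x", "x", "y", "y", "y", "z", "z"),
           c(20, 5, 5, 30, 5, 5, 10))
  b <- rep(c("x", "y", "x", "y", "z", "y", "z"),
           c(20, 5, 5, 30, 5, 5, 10))
  expect_equal(cohen_kappa(a, b), 0.3671875 / 0.6171875, tolerance = 1e-12)

  # independent uniform labels agree only by chance
  withr::with_seed(77, {
    u <- sample(letters[1:3], 10000, replace = TRUE)
    v <- sample(letters[1:3], 10000, replace = TRUE)
  })
  expect_lt(abs(cohen_kappa(u, v)), 0.1)
})
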