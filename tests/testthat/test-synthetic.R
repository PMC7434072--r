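test_that("generation is fully deterministic under the seed", {
  cfg <- synth_config(seed = 51, n_users = 15, years = 2014,
                      n_background_docs = 40)
  expect_identical(generate_background(cfg), generate_background(cfg))
  f1 <- generate_forum(cfg)
  f2 <- generate_forum(cfg)
  expect_identical(as.data.frame(f1$messages), as.data.frame(f2$messages))
  expect_identical(f1$truth$message_truth$themes,
                   f2$truth$message_truth$themes)
  cfg2 <- synth_config(seed = 52, n_users = 15, years = 2014,
                       n_background_docs = 40)
  expect_false(identical(generate_background(cfg), generate_background(cfg2)))
})

test_that("config invariants are enforced", {
  expect_error(synth_config(archetype_mix = c(initiator = 0.5, attractor = 0.2,
                                              poster = 0.2, background = 0.2)),
               "sum to 1")
  expect_error(synth_config(thread_rates = c(initiator = -1, attractor = 1,
                                             poster = 1, background = 1)),
               "non-negative")
  expect_error(synth_config(neologisms = tibble::tibble(
    token = "fill001", anchor_theme = "self_belief", rate = 0.3)),
    "absent from the background")
  expect_error(synth_config(n_filler = 0), "non-empty")
})

test_that("neologisms never enter the background corpus", {
  fx <- study_fixture()
  bg_tokens <- unique(unlist(tokenize(fx$background)))
  expect_false(any(fx$config$neologisms$token %in% bg_tokens))
  # but they do occur in the forum corpus
  forum_tokens <- unique(unlist(tokenize(fx$messages$body)))
  expect_true(all(fx$config$neologisms$token %in% forum_tokens))
})

test_that("every message contains tokens from each of its true themes", {
  forum <- small_forum()
  cfg <- forum$config
  toks <- tokenize(forum$messages$body)
  truth <- forum$truth$message_truth
  ok <- purrr::map2_lgl(toks, truth$themes, function(t, ths) {
    all(purrr::map_lgl(ths, ~ any(cfg$theme_tokens[[.x]] %in% t)))
  })
  expect_true(all(ok))
})

test_that("filler token frequencies follow the configured Zipf law", {
  fx <- study_fixture()
  cfg <- fx$config
  counts <- table(unlist(tokenize(fx$background)))
  top <- cfg$filler_tokens[1:200]   # generator rank order
  obs <- as.numeric(counts[top])
  fit <- stats::lm(log(obs) ~ log(seq_along(top)))
  slope <- unname(stats::coef(fit)[2])
  expect_lt(abs(-slope - cfg$zipf_exponent) / cfg$zipf_exponent, 0.1)
})

test_that("realized activity reproduces the archetype rate ordering", {
  cfg <- synth_config(seed = 61, n_users = 250, years = 2014,
                      n_background_docs = 20)
  forum <- generate_forum(cfg)
  prof <- compute_profiles(forum$messages)
  arch <- setNames(forum$truth$user_truth$archetype,
                   forum$truth$user_truth$user_id)
  prof$arch <- arch[prof$user_id]
  means <- prof |>
    dplyr::group_by(arch) |>
    dplyr::summarise(threads = mean(threads_initiated), posts = mean(posts),
                     replies = mean(replies_attracted), .groups = "drop")
  m <- function(a, col) means[[col]][means$arch == a]
  expect_gt(m("initiator", "threads"), max(m("attractor", "threads"),
                                           m("poster", "threads"),
                                           m("background", "threads")))
  expect_gt(m("poster", "posts"), max(m("initiator", "posts"),
                                      m("attractor", "posts"),
                                      m("background", "posts")))
  expect_gt(m("attractor", "replies"), max(m("initiator", "replies"),
                                           m("poster", "replies"),
                                           m("background", "replies")))
})

test_that("corpus and ground truth are referentially complete", {
  forum <- small_forum()
  expect_setequal(forum$messages$message_id,
                  forum$truth$message_truth$message_id)
  expect_setequal(forum$users$user_id, forum$truth$user_truth$user_id)
  expect_true(all(forum$messages$sender_id %in% forum$users$user_id))
})

test_that("doubling activity rates roughly doubles realized counts", {
  base <- synth_config(seed = 71, n_users = 150, years = 2014,
                       n_background_docs = 20)
  doubled <- synth_config(seed = 71, n_users = 150, years = 2014,
                          n_background_docs = 20,
                          thread_rates = 2 * base$thread_rates,
                          reply_rates = 2 * base$reply_rates)
  n1 <- nrow(generate_forum(base)$messages)
  n2 <- nrow(generate_forum(doubled)$messages)
  expect_gt(n2 / n1, 1.8)
  expect_lt(n2 / n1, 2.2)
})

test_that("the written bundle round-trips through the exchange formats", {
  fx <- study_fixture()
  dir <- withr::local_tempdir()
  small <- list(config = fx$config,
                messages = fx$messages[1:50, ],
                users = fx$users,
                annotations = fx$annotations[1:20, ],
                background = fx$background[1:30],
                truth = list(message_truth =
                               fx$truth$message_truth[1:50, ]))
  paths <- write_synthetic_bundle(small, dir)
  expect_true(all(file.exists(paths)))
  back <- read_messages(paths[["messages"]])
  expect_equal(as.data.frame(back), as.data.frame(small$messages))
  ann <- read_annotations(paths[["annotations"]])
  expect_setequal(unique(ann$message_id),
                  unique(small$annotations$message_id))
  cfg <- yaml::read_yaml(paths[["config"]])
  expect_equal(cfg$seed, fx$config$seed)
})
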