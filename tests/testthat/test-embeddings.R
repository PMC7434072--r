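test_that("skip-gram training covers the retained vocabulary and is seed-deterministic", {
  docs <- rep(c("red apple tree red apple", "blue fish swim blue fish deep"), 30)
  cfg <- sgns_config(dimension = 10, min_count = 1, epochs = 3, seed = 5)
  store <- train_background(docs, cfg)
  expect_s3_class(store, "vector_store")
  expect_equal(ncol(store), 10)
  expect_setequal(rownames(store),
                  c("red", "apple", "tree", "blue", "fish", "swim", "deep"))
  expect_true(all(abs(sqrt(rowSums(unclass(store)^2)) - 1) < 1e-6))

  again <- train_background(docs, cfg)
  expect_identical(unclass(store), unclass(again))
  other <- train_background(docs, sgns_config(dimension = 10, min_count = 1,
                                              epochs = 3, seed = 6))
  expect_false(identical(unclass(store), unclass(other)))

  expect_error(train_background("nothing here", sgns_config(min_count = 50)),
               "vocabulary is empty")
})

test_that("heavily co-occurring terms embed closer than typical pairs", {
  stores <- fixture_stores()
  bg <- stores$background
  set.seed(11)
  pairs <- t(replicate(1500, sample(rownames(bg), 2)))
  rnd <- store_cosine(bg, pairs[, 1], pairs[, 2])
  expect_gt(store_cosine(bg, "hammock", "relaxing"), stats::median(rnd))
})

test_that("planted paraphrase pairs rank above random pairs with AUC >= 0.9", {
  fx <- study_fixture()
  bg <- fixture_stores()$background
  within <- unlist(purrr::map(fx$config$theme_tokens, function(tok) {
    tok <- intersect(tok, rownames(bg))
    if (length(tok) < 2) return(NULL)
    utils::combn(tok, 2, function(p) store_cosine(bg, p[1], p[2]))
  }))
  set.seed(12)
  pairs <- t(replicate(2000, sample(rownames(bg), 2)))
  rnd <- store_cosine(bg, pairs[, 1], pairs[, 2])
  auc <- mean(outer(within, rnd, ">") + 0.5 * outer(within, rnd, "=="))
  expect_gte(auc, 0.9)
})

test_that("stage-1 vectors equal brute-force superposition of background vectors", {
  fx <- study_fixture()
  stores <- fixture_stores()
  bg <- stores$background
  s1 <- stores$stage1
  set.seed(13)
  ids <- sample(fx$messages$message_id, 50)
  toks <- tokenize(fx$messages$body[match(ids, fx$messages$message_id)],
                   stopwords = fx$stopwords, drop_numeric = TRUE)
  for (i in seq_along(ids)) {
    t_in <- toks[[i]][toks[[i]] %in% rownames(bg)]
    v <- rep(0, ncol(bg))
    for (tk in t_in) v <- v + unclass(bg)[tk, ]   # multiplicity counted
    nrm <- sqrt(sum(v^2))
    if (nrm > 0) v <- v / nrm
    expect_equal(unname(unclass(s1)[ids[i], ]), unname(v), tolerance = 1e-12)
  }
})

test_that("stage-1 handles identity and out-of-vocabulary messages", {
  docs <- rep("alpha beta gamma delta alpha beta", 20)
  bg <- train_background(docs, sgns_config(dimension = 8, min_count = 1,
                                           epochs = 2, seed = 3))
  msgs <- make_messages(c("m1", "m2", "m3"), "t1", "u")
  msgs$body <- c("alpha", "zzz qqq www", "alpha beta")
  s1 <- stage1_message_vectors(bg, msgs)
  expect_equal(unname(unclass(s1)["m1", ]), unname(unclass(bg)["alpha", ]),
               tolerance = 1e-12)
  expect_equal(unname(unclass(s1)["m2", ]), rep(0, 8))
  expect_identical(attr(s1, "flagged"), "m2")
})

test_that("corpus term vectors equal a brute-force inverted index (presence semantics)", {
  fx <- study_fixture()
  stores <- fixture_stores()
  s1 <- stores$stage1
  msgs <- fx$messages[1:100, ]
  ct <- corpus_term_vectors(s1, msgs, min_count = 2)
  toks <- tokenize(msgs$body, stopwords = fx$stopwords, drop_numeric = TRUE)
  set.seed(14)
  for (term in sample(rownames(ct), 25)) {
    in_msgs <- msgs$message_id[purrr::map_lgl(toks, ~ term %in% .x)]
    v <- colSums(unclass(s1)[in_msgs, , drop = FALSE])
    nrm <- sqrt(sum(v^2))
    if (nrm > 0) v <- v / nrm
    expect_equal(unname(unclass(ct)[term, ]), unname(v), tolerance = 1e-12)
  }
  # a term occurring in exactly one message inherits that message vector
  msg_count <- table(unlist(purrr::map(toks, unique)))
  singles <- intersect(rownames(ct), names(msg_count[msg_count == 1]))
  if (length(singles) > 0) {
    term <- singles[1]
    host <- msgs$message_id[purrr::map_lgl(toks, ~ term %in% .x)]
    expect_equal(unname(unclass(ct)[term, ]),
                 unname(unclass(s1)[host, ]), tolerance = 1e-12)
  }
})

test_that("neologisms absent from the background acquire corpus vectors", {
  fx <- study_fixture()
  stores <- fixture_stores()
  expect_false(any(fx$config$neologisms$token %in%
                     rownames(stores$background)))
  expect_true(all(fx$config$neologisms$token %in%
                    rownames(stores$corpus_terms)))
})

test_that("stage-2 vectors are bag-of-words and sharpen synonym similarity", {
  fx <- study_fixture()
  stores <- fixture_stores()
  ct <- stores$corpus_terms
  tok <- intersect(fx$config$theme_tokens$social_support, rownames(ct))
  msgs <- make_messages(c("a", "b", "bp"), "t1", "u")
  msgs$body <- c(paste(tok[1:3], collapse = " "),
                 paste(tok[4:6], collapse = " "),
                 paste(rev(tok[4:6]), collapse = " "))
  s2 <- stage2_message_vectors(ct, msgs)
  # permuting token order leaves the vector unchanged
  expect_equal(unclass(s2)["b", ], unclass(s2)["bp", ], tolerance = 1e-12,
               ignore_attr = TRUE)
  # one-token message inherits the term vector
  one <- make_messages("solo", "t1", "u")
  one$body <- tok[1]
  expect_equal(unname(unclass(stage2_message_vectors(ct, one))["solo", ]),
               unname(unclass(ct)[tok[1], ]), tolerance = 1e-12)
  # disjoint same-theme vocabulary: stage 2 rates them closer than stage 1
  bg <- stores$background
  s1 <- stage1_message_vectors(bg, msgs[1:2, ])
  cos1 <- sum(unclass(s1)["a", ] * unclass(s1)["b", ])
  cos2 <- sum(unclass(s2)["a", ] * unclass(s2)["b", ])
  expect_gt(cos2, cos1)
})

test_that("superposition is additive before normalization", {
  stores <- fixture_stores()
  bg <- stores$background
  vocab <- rownames(bg)
  msgs <- make_messages(c("ab", "a", "b"), "t1", "u")
  msgs$body <- c(paste(vocab[1:6], collapse = " "),
                 paste(vocab[1:3], collapse = " "),
                 paste(vocab[4:6], collapse = " "))
  toks <- tokenize(msgs$body)
  inc <- forumscope:::incidence_matrix(toks, msgs$message_id, vocab)
  raw <- as.matrix(inc %*% unclass(bg))
  expect_equal(raw["ab", ], raw["a", ] + raw["b", ], tolerance = 1e-12)
})

test_that("normalization is idempotent and self-similarity is 1", {
  stores <- fixture_stores()
  s2 <- stores$stage2
  expect_equal(unclass(normalize_rows(s2)), unclass(s2), tolerance = 1e-12)
  set.seed(15)
  ids <- sample(rownames(s2), 20)
  expect_equal(store_cosine(s2, ids, ids), rep(1, 20), tolerance = 1e-6)
  pairs <- t(replicate(200, sample(rownames(s2), 2)))
  cc <- store_cosine(s2, pairs[, 1], pairs[, 2])
  expect_true(all(cc >= -1 - 1e-12 & cc <= 1 + 1e-12))
})

test_that("one superposition cycle reproduces the explicit three-stage path", {
  fx <- study_fixture()
  stores <- fixture_stores()
  msgs <- fx$messages[1:200, ]
  cyc <- superposition_cycle(stores$background, msgs, iterations = 1,
                             min_count = 2)
  s1 <- stage1_message_vectors(stores$background, msgs)
  ct <- corpus_term_vectors(s1, msgs, min_count = 2)
  s2 <- stage2_message_vectors(ct, msgs)
  expect_identical(unclass(cyc$stage2), unclass(s2))
  # extra iterations keep vectors unit-norm and dimensions aligned
  cyc2 <- superposition_cycle(stores$background, msgs, iterations = 2,
                              min_count = 2)
  nrm <- sqrt(rowSums(unclass(cyc2$stage2)^2))
  expect_true(all(abs(nrm[nrm > 0] - 1) < 1e-6))
  expect_false(identical(unclass(cyc2$stage2), unclass(s2)))
})

test_that("all pipeline stores share the declared dimension", {
  stores <- fixture_stores()
  dims <- purrr::map_int(stores, ncol)
  expect_true(all(dims == dims[1]))
})

test_that("vector stores round-trip through the word2vec text format", {
  stores <- fixture_stores()
  s1 <- stores$stage1
  sub <- vector_store(unclass(s1)[1:25, ], provenance = "stage1_messages",
                      config = attr(s1, "config"),
                      flagged = attr(s1, "flagged"))
  path <- withr::local_tempfile(fileext = ".vec")
  write_vector_store(sub, path)
  back <- read_vector_store(path)
  expect_equal(unclass(back), unclass(sub), tolerance = 1e-15)
  expect_identical(attr(back, "provenance"), "stage1_messages")
  expect_identical(attr(back, "config")$seed, attr(sub, "config")$seed)
})
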