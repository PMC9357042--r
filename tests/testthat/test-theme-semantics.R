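test_that("embedding loader enforces the text-format contract", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("cat 1 0 0 0.5", "dog 0 1 0 0", "mat 0.2 0.2 0.2 0.2"), tmp)
  emb <- load_embeddings(tmp)
  expect_equal(dim(emb), c(3, 4))
  expect_equal(rownames(emb), c("cat", "dog", "mat"))
  expect_equal(unname(emb["cat", ]), c(1, 0, 0, 0.5))

  emb_f <- load_embeddings(tmp, vocab_filter = c("dog", "absent"))
  expect_equal(rownames(emb_f), "dog")

  writeLines(c("cat 1 0 0 0.5", "dog 0 1 0"), tmp)
  expect_error(load_embeddings(tmp), "line 2")
  writeLines(c("cat 1 0", "dog 0 x"), tmp)
  expect_error(load_embeddings(tmp), "line 2.*non-numeric")
  writeLines(c("cat 1 0", "dog 0 0"), tmp)
  expect_error(load_embeddings(tmp), "line 2.*zero vector")
})

test_that("generated embeddings round-trip exactly through the text format", {
  toks <- sprintf("t%02d", 1:12)
  emb <- generate_embeddings(toks, setNames(rep(c("a", "b"), 6), toks),
                             dim = 7, concentration = 3, seed = 4)
  tmp <- withr::local_tempfile(fileext = ".txt")
  write_embeddings(emb, tmp)
  back <- load_embeddings(tmp)
  expect_identical(unname(back), unname(emb))
  expect_identical(rownames(back), rownames(emb))
})

test_that("theme-word selection counts, excludes, and leaves one out", {
  emb <- axis_embeddings(c("murder", "river", "beer", "girl", "claire",
                           "stuart", "body", "x"))
  parts <- tibble::tibble(
    participant_id = sprintf("p%02d", 1:10),
    theme_words = c(rep(list(c("murder", "river", "beer")), 7),
                    rep(list(c("murder", "river", "x")), 2),
                    list(c("girl", "murder"))))

  # top-k by frequency: murder 10, river 9, beer 7
  th <- select_theme_words(parts, emb, k = 3)
  expect_equal(th$tokens, c("murder", "river", "beer"))

  # unanimity: everyone generates the same words -> those words, any leave_out
  uni <- tibble::tibble(participant_id = sprintf("p%02d", 1:5),
                        theme_words = rep(list(c("murder", "river")), 5))
  expect_equal(select_theme_words(uni, emb, k = 2)$tokens,
               c("murder", "river"))
  expect_equal(select_theme_words(uni, emb, k = 2, leave_out = "p01")$tokens,
               c("murder", "river"))

  # proper nouns and cue words in the exclusion set never appear
  parts2 <- tibble::tibble(
    participant_id = sprintf("p%02d", 1:6),
    theme_words = rep(list(c("claire", "stuart", "body", "murder", "girl")), 6))
  expect_warning(
    th2 <- select_theme_words(parts2, emb, k = 10,
                              exclusions = c("Claire", "Stuart", "body")),
    "survive")
  expect_false(any(c("claire", "stuart", "body") %in% th2$tokens))
  expect_true(all(c("murder", "girl") %in% th2$tokens))
  expect_true(th2$provenance$short)

  # leave-one-out removes that participant's contribution from the counts
  parts3 <- tibble::tibble(
    participant_id = c("p01", "p02", "p03"),
    theme_words = list(c("beer"), c("girl"), c("girl")))
  expect_equal(select_theme_words(parts3, emb, k = 1)$tokens, "girl")
  # dropping p02 leaves girl and beer tied; ties break alphabetically
  expect_equal(select_theme_words(parts3, emb, k = 1,
                                  leave_out = "p02")$tokens, "beer")
})

test_that("theme-word ties break alphabetically", {
  emb <- axis_embeddings(c("apple", "zebra", "mango"))
  parts <- tibble::tibble(participant_id = c("p1", "p2"),
                          theme_words = list(c("zebra", "apple", "mango"),
                                             c("zebra", "apple", "mango")))
  th <- select_theme_words(parts, emb, k = 2)
  expect_equal(th$tokens, c("apple", "mango"))
})

test_that("theme similarity is the maximal cosine and is scale invariant", {
  emb <- axis_embeddings(c("t1", "t2", "o"))
  themes <- make_themes(emb, c("t1", "t2"))

  expect_equal(theme_similarity(emb["t1", ], themes), 1)
  expect_equal(theme_similarity(emb["o", ], themes), 0)
  expect_equal(theme_similarity(c(1, 1, 0), themes), 1 / sqrt(2),
               tolerance = 1e-12)

  set.seed(2)
  a <- rnorm(3)
  expect_equal(theme_similarity(5.5 * a, themes), theme_similarity(a, themes),
               tolerance = 1e-12)

  # duplicated theme vector never changes the max
  themes_dup <- make_themes(rbind(emb, t1b = emb["t1", ]),
                            c("t1", "t2", "t1b"))
  expect_equal(theme_similarity(a, themes_dup), theme_similarity(a, themes),
               tolerance = 1e-12)

  expect_error(theme_similarity(c(0, 0, 0), themes), "zero")
})

test_that("chain scoring averages in-vocabulary tokens and drops OOV", {
  emb <- axis_embeddings(c("t", "o"))
  themes <- make_themes(emb, "t")

  expect_equal(chain_theme_similarity("t", emb, themes),
               list(mean = 1, n_scored = 1L))
  # [theme, OOV, orthogonal]: mean of {1, 0}, OOV out of both sides
  r <- chain_theme_similarity(c("t", "missing", "o"), emb, themes)
  expect_equal(r$mean, 0.5)
  expect_equal(r$n_scored, 2L)
  # all OOV -> flagged missing
  r0 <- chain_theme_similarity(c("gone", "absent"), emb, themes)
  expect_true(is.na(r0$mean))
  expect_equal(r0$n_scored, 0L)
})

test_that("chain scoring equals a nested-loop brute force", {
  set.seed(13)
  toks <- sprintf("t%02d", 1:30)
  emb <- generate_embeddings(toks, setNames(rep(c("a", "b", "c"), 10), toks),
                             dim = 12, concentration = 2, seed = 6)
  themes <- make_themes(emb, toks[1:5])
  chain <- sample(c(toks, "oov1", "oov2"), 60, replace = TRUE)

  got <- chain_theme_similarity(chain, emb, themes)

  sims <- c()
  for (tk in chain) {
    if (!tk %in% rownames(emb)) next
    best <- -Inf
    for (th in themes$tokens) {
      a <- emb[tk, ]; b <- emb[th, ]
      cs <- sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
      if (cs > best) best <- cs
    }
    sims <- c(sims, best)
  }
  expect_equal(got$mean, mean(sims), tolerance = 1e-12)
  expect_equal(got$n_scored, length(sims))
})

test_that("pre/post delta reflects added theme content", {
  emb <- axis_embeddings(c("t", "o", "u"))
  themes <- make_themes(emb, "t")
  same <- prepost_theme_delta(c("o", "u"), c("o", "u"), emb, themes)
  expect_equal(same$delta, 0)
  more <- prepost_theme_delta(c("o", "u"), c("o", "u", "t"), emb, themes)
  expect_gt(more$delta, 0)
})

test_that("chain mean is order-invariant but the timecourse is not", {
  set.seed(42)
  toks <- c(sprintf("th%02d", 1:5), sprintf("b%02d", 1:20))
  emb <- generate_embeddings(
    toks, setNames(rep(c("theme", "bg"), c(5, 20)), toks),
    dim = 10, concentration = 50, seed = 9)
  themes <- make_themes(emb, toks[1:5])

  front <- c(rep("th01", 10), rep("b01", 10))  # theme tokens in bin 1
  back <- rev(front)                            # theme tokens in bin 2
  expect_equal(chain_theme_similarity(front, emb, themes)$mean,
               chain_theme_similarity(back, emb, themes)$mean,
               tolerance = 1e-12)

  mk <- function(post) make_chains(lapply(1:6, function(i)
    list(pre = rep("b01", 20), post = post)))
  tc_front <- timecourse(mk(front), emb, themes)
  tc_back <- timecourse(mk(back), emb, themes)
  expect_false(isTRUE(all.equal(tc_front$bins$d, tc_back$bins$d)))
})

test_that("timecourse bins, converts to seconds, and flags significance", {
  emb <- axis_embeddings(c("t", "o"))
  themes <- make_themes(emb, "t")

  # identical pre and post chains: every bin d = 0, CI spans 0
  chains <- make_chains(lapply(1:8, function(i) {
    toks <- rep(c("t", "o"), 10)
    list(pre = toks, post = toks)
  }))
  tc <- timecourse(chains, emb, themes)
  expect_equal(tc$seconds_per_bin, 48.88)
  expect_true(all(tc$bins$d == 0))
  expect_true(all(tc$bins$lower <= 0 & tc$bins$upper >= 0))
  expect_false(any(tc$bins$significant))
  dur <- lingering_duration(tc)
  expect_equal(dur$n_significant_bins, 0)
  expect_equal(dur$seconds, 0)

  # participants contribute to a bin only when both phases complete it
  mixed <- make_chains(list(
    list(pre = rep("o", 25), post = rep("o", 25)),   # bins 1-2
    list(pre = rep("o", 25), post = rep("o", 12)),   # bin 1 only (post short)
    list(pre = rep("o", 15), post = rep("o", 30)),   # bin 1 only (pre short)
    list(pre = rep("o", 25), post = rep("o", 25))))
  tcm <- timecourse(mixed, emb, themes)
  expect_equal(tcm$bins$n[tcm$bins$bin == 1], 4)
  expect_true(all(tcm$bins$bin <= 2))

  # chains shorter than one bin everywhere: rejected
  tiny <- make_chains(list(list(pre = rep("o", 4), post = rep("o", 4)),
                           list(pre = rep("o", 4), post = rep("o", 4)),
                           list(pre = rep("o", 4), post = rep("o", 4))))
  expect_error(timecourse(tiny, emb, themes), "first bin")
})

test_that("lingering duration converts significant bins to seconds", {
  # strong early injection: first bins significant, duration = count x 48.88
  set.seed(3)
  toks <- c(sprintf("th%02d", 1:5), sprintf("b%02d", 1:30))
  emb <- generate_embeddings(
    toks, setNames(rep(c("theme", "bg"), c(5, 30)), toks),
    dim = 16, concentration = 20, seed = 11)
  themes <- make_themes(emb, toks[1:5])
  chains <- make_chains(lapply(1:12, function(i) {
    pre <- sample(toks[6:35], 30, replace = TRUE)
    post <- c(sample(toks[1:5], 10, replace = TRUE),
              sample(toks[6:35], 20, replace = TRUE))
    list(pre = pre, post = post)
  }))
  tc <- timecourse(chains, emb, themes)
  dur <- lingering_duration(tc)
  expect_gte(dur$n_significant_bins, 1)
  expect_equal(dur$seconds, dur$n_significant_bins * 48.88)
  expect_true(tc$bins$significant[tc$bins$bin == 1])
})

test_that("delta on null cohorts is centred at zero", {
  # pool participants over several seeded null cohorts: the pooled mean
  # delta must sit within 2 SE of zero
  deltas <- unlist(lapply(1:8, function(s) {
    coh <- generate_cohort(small_null_config(seed = 50 + s, n = 25,
                                             delta = 0, vocab = 80, len = 30))
    themes <- select_theme_words(coh, coh$embeddings, k = 5)
    cohort_theme_deltas(coh$chains, coh$embeddings, themes)$delta
  }))
  se <- sd(deltas) / sqrt(length(deltas))
  expect_lt(abs(mean(deltas)), 2 * se + 1e-9)
})
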