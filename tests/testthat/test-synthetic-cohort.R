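test_that("clustered embeddings have the promised cosine geometry", {
  # one cluster, near-zero noise: all pairwise cosines ~ 1
  emb <- generate_embeddings(letters[1:6], setNames(rep("k", 6), letters[1:6]),
                             dim = 10, concentration = 1e6, seed = 1)
  cs <- tcrossprod(emb / sqrt(rowSums(emb^2)))
  expect_true(all(cs[upper.tri(cs)] > 0.999))

  # two clusters with orthogonal centers, tight: between-cluster cosine ~ 0
  centers <- rbind(a = c(1, 0, 0, 0), b = c(0, 1, 0, 0))
  toks <- sprintf("t%02d", 1:20)
  cl <- setNames(rep(c("a", "b"), each = 10), toks)
  emb <- generate_embeddings(toks, cl, dim = 4, concentration = 100,
                             seed = 2, centers = centers)
  u <- emb / sqrt(rowSums(emb^2))
  between <- tcrossprod(u[1:10, ], u[11:20, ])
  expect_lt(abs(mean(between)), 0.02)

  # 3 clusters x 20 tokens: within > between by brute-force pairwise cosines
  toks <- sprintf("w%02d", 1:60)
  cl <- setNames(rep(c("a", "b", "c"), each = 20), toks)
  emb <- generate_embeddings(toks, cl, dim = 50, concentration = 10, seed = 1)
  u <- emb / sqrt(rowSums(emb^2))
  cos_all <- tcrossprod(u)
  same <- outer(cl, cl, "==")
  ut <- upper.tri(cos_all)
  expect_gt(mean(cos_all[ut & same]), mean(cos_all[ut & !same]))

  # determinism
  expect_identical(emb, generate_embeddings(toks, cl, 50, 10, seed = 1))
})

test_that("embedding generation rejects bad inputs", {
  expect_error(generate_embeddings(c("a", "a"), c(a = "k"), 5, 1, 1),
               "duplicate")
  expect_error(generate_embeddings("a", c(a = "k"), 1, 1, 1), ">= 2")
  expect_error(generate_embeddings(c("a", "b"), c(a = "k"), 5, 1, 1),
               "cluster")
})

test_that("chain injection follows the decaying-probability model", {
  base <- setNames(rep(0.1, 10), paste0("b", 1:10))
  themes <- paste0("th", 1:3)

  # delta = 0: post is generated exactly like pre (same RNG consumption)
  set.seed(5); pre <- generate_chain("pre", length = 40, base_distribution = base)
  set.seed(5); post0 <- generate_chain("post", delta = 0, length = 40,
                                       base_distribution = base)
  expect_identical(pre$tokens, post0$tokens)

  # delta = 1, lambda = 0: every token is a theme token
  set.seed(6)
  all_in <- generate_chain("post", delta = 1, lambda = 0, length = 10,
                           base_distribution = base, theme_tokens = themes)
  expect_true(all(all_in$tokens %in% themes))

  expect_error(generate_chain("post", delta = 1.2, length = 5,
                              base_distribution = base), "\\[0, 1\\]")
  expect_error(generate_chain("pre", length = 5,
                              base_distribution = base * 2), "sum to 1")
})

test_that("expected injected-token count matches its closed form", {
  # closed form equals the direct per-position sum
  direct <- sum(0.5 * exp(-0.1 * (0:59)))
  expect_equal(expected_injected(0.5, 0.1, 60), direct, tolerance = 1e-12)
  expect_equal(expected_injected(0.3, 0, 40), 12)

  # Monte Carlo agreement within 2 SE (10,000 chains)
  base <- setNames(rep(1 / 20, 20), paste0("b", 1:20))
  themes <- paste0("th", 1:5)
  set.seed(99)
  counts <- replicate(10000, {
    ch <- generate_chain("post", delta = 0.5, lambda = 0.1, length = 60,
                         base_distribution = base, theme_tokens = themes)
    sum(ch$tokens %in% themes)
  })
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - direct), 2 * se + 1e-9)
})

test_that("theme-token prevalence is monotone in the injection rate", {
  base <- setNames(rep(1 / 20, 20), paste0("b", 1:20))
  themes <- paste0("th", 1:5)
  set.seed(17)
  prev <- sapply(c(0, 0.1, 0.3, 0.6), function(d) {
    mean(replicate(1000, {
      ch <- generate_chain("post", delta = d, lambda = 0.05, length = 30,
                           base_distribution = base, theme_tokens = themes)
      mean(ch$tokens %in% themes)
    }))
  })
  expect_true(all(diff(prev) >= 0))
})

test_that("cohort generation is deterministic and carries its ground truth", {
  cfg <- small_null_config(seed = 3, n = 8, delta = 0.3, lambda = 0.1,
                           vocab = 60, len = 15)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$chains, b$chains)
  expect_identical(a$participants, b$participants)
  expect_identical(a$embeddings, b$embeddings)

  # realized deltas sit within the jitter band of the condition delta
  gt <- a$ground_truth$delta
  expect_true(all(abs(gt$delta - 0.3) <= cfg$delta_jitter + 1e-12))

  # exactly one pre and one post chain per participant
  per <- table(unique(a$chains[, c("participant_id", "phase")])$participant_id)
  expect_true(all(per == 2))

  # every chain token has an embedding row (no deliberate OOV configured)
  expect_true(all(unique(a$chains$token) %in% rownames(a$embeddings)))
})

test_that("deliberate OOV tokens are flagged in the ground truth", {
  cfg <- synthetic_config(n_participants_per_condition = 6,
                          conditions = list(c1 = list(delta = 0, lambda = 0)),
                          chain_length_mean = 20, vocab_size_base = 40,
                          embedding_dim = 10, n_oov = 5, seed = 2)
  coh <- generate_cohort(cfg)
  oov <- coh$ground_truth$oov_tokens
  expect_length(oov, 5)
  expect_false(any(oov %in% rownames(coh$embeddings)))
  in_chain <- unique(coh$chains$token)
  expect_true(all(in_chain %in% c(rownames(coh$embeddings), oov)))
})

test_that("self-report signal tracks the condition injection gradient", {
  # no signal: condition uninformative about lingering when all deltas are 0
  cfg0 <- synthetic_config(
    n_participants_per_condition = 50,
    conditions = list(a = list(delta = 0, lambda = 0),
                      b = list(delta = 0, lambda = 0),
                      c = list(delta = 0, lambda = 0)),
    chain_length_mean = 3, vocab_size_base = 30, embedding_dim = 10, seed = 8)
  coh0 <- generate_cohort(cfg0)
  rho <- cor(as.integer(factor(coh0$participants$condition)),
             coh0$participants$lingering_rating, method = "spearman")
  expect_lt(abs(rho), 0.15)

  # graded deltas: median lingering ordered with delta in every seeded cohort
  ok <- sapply(1:30, function(s) {
    cfg <- synthetic_config(
      n_participants_per_condition = 40,
      conditions = list(intact = list(delta = 0.40, lambda = 0.05),
                        sentence = list(delta = 0.20, lambda = 0.05),
                        word = list(delta = 0.05, lambda = 0.05)),
      chain_length_mean = 3, vocab_size_base = 30, embedding_dim = 10,
      seed = s)
    med <- tapply(generate_cohort(cfg)$participants$lingering_rating,
                  generate_cohort(cfg)$participants$condition, median)
    med[["intact"]] >= med[["sentence"]] && med[["sentence"]] >= med[["word"]]
  })
  expect_gte(mean(ok), 0.9)
})

test_that("word-list fixture has exact flag counts and scannable decoy gaps", {
  wl <- generate_word_list(268, frac_italic = 0.25, frac_decoy = 0.25, seed = 7)
  expect_equal(sum(wl$italic), 67)
  expect_equal(sum(wl$italic) / nrow(wl), 0.25, tolerance = 0.002)
  expect_equal(sum(wl$role == "decoy"), 67)
  # italics only on story words
  expect_true(all(wl$role[wl$italic] == "story"))
  # first 15 items are story words
  expect_true(all(wl$role[1:15] == "story"))

  expect_equal(sum(generate_word_list(4, frac_italic = 0, seed = 1)$italic), 0)
  expect_error(generate_word_list(10, frac_italic = 0.9, frac_decoy = 0.5,
                                  seed = 1), "italic")

  # mean inter-decoy gap: diff of decoy positions agrees with a direct
  # recount of story words lying between the first and last decoy
  pos <- wl$position[wl$role == "decoy"]
  gaps_scan <- diff(pos) - 1
  expect_true(is.finite(mean(gaps_scan)) && mean(gaps_scan) > 0)
  expect_equal(sum(gaps_scan), sum(wl$role[min(pos):max(pos)] == "story"))
})
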