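# Shared fixtures, built in code at test time.

# Minimal chains tibble: one participant per element of `tokens`, each a
# list(pre = c(...), post = c(...)).
make_chains <- function(tokens, condition = "c1") {
  rows <- lapply(seq_along(tokens), function(i) {
    pid <- sprintf("p%02d", i)
    pre <- tokens[[i]]$pre
    post <- tokens[[i]]$post
    tibble::tibble(
      participant_id = pid, condition = condition,
      phase = rep(c("pre", "post"), c(length(pre), length(post))),
      position = c(seq_along(pre), seq_along(post)),
      token = c(pre, post),
      latency_ms = 1000)
  })
  do.call(rbind, rows)
}

# Orthonormal toy embeddings: each token gets one axis of R^n.
axis_embeddings <- function(tokens) {
  emb <- diag(length(tokens))
  rownames(emb) <- tokens
  emb
}

# Theme set straight from an embedding matrix (bypasses frequency counting).
make_themes <- function(embeddings, tokens) {
  structure(list(tokens = tokens,
                 vectors = embeddings[tokens, , drop = FALSE],
                 provenance = list(frequencies = NULL,
                                   exclusions = character(),
                                   leave_out = NULL, short = FALSE)),
            class = "linger_themes")
}

# Small single-condition cohort for classification tests.
small_null_config <- function(seed, n = 30, delta = 0, lambda = 0,
                              vocab = 150, len = 30) {
  synthetic_config(
    n_participants_per_condition = n,
    conditions = list(c1 = list(delta = delta, lambda = lambda)),
    chain_length_mean = len, vocab_size_base = vocab,
    embedding_dim = 20, seed = seed)
}

scaled_dtm_of <- function(cohort) scale_dtm(build_dtm(cohort$chains))
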