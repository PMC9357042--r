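#' Configuration for a synthetic free-association cohort
#'
#' Bundles every tunable of the cohort generator. Defaults emulate the design
#' of a three-condition reading study: 80 participants per condition, two
#' ~60-token free-association chains each (one pre-, one post-exposure,
#' ~4888 ms per associate, i.e. roughly five minutes of production), and a
#' condition-graded "lingering" effect in which theme-related tokens are
#' injected into post chains with a probability that decays exponentially
#' with token position.
#'
#' @param n_participants_per_condition Participants per condition (default 80).
#' @param conditions Named list; each element a list with `delta` (injection
#'   rate at position 1, in `[0,1]`) and `lambda` (exponential decay rate per
#'   position, `>= 0`). The default three levels mirror decreasing narrative
#'   coherence: `intact` (delta 0.40), `sentence` (0.20), `word` (0.05), all
#'   with lambda 0.05 (e-folding over ~20 associates, about two 10-associate
#'   bins).
#' @param chain_length_mean Mean chain length in tokens (default 60).
#' @param chain_length_dispersion Negative-binomial size parameter; smaller
#'   values give more short chains (default 40).
#' @param token_latency_mean_ms Mean per-token production latency (default
#'   4888 ms).
#' @param latency_shape Gamma shape for latency dispersion (default 12).
#' @param vocab_size_base Number of background vocabulary tokens (default 500).
#' @param theme_cluster_size Number of tokens in the theme cluster (default 10).
#' @param n_background_clusters Semantic clusters among background tokens
#'   (default 8).
#' @param embedding_dim Embedding dimension (default 50; use 300 for realism).
#' @param cluster_concentration Within-cluster tightness; embedding noise has
#'   expected norm `1/cluster_concentration` (default 2).
#' @param selfreport_noise_sd SD of the Gaussian noise added to the latent
#'   lingering score before rounding to the 1-7 scale (default 1).
#' @param delta_jitter Half-width of the uniform per-participant jitter on the
#'   condition injection rate (default 0.05).
#' @param lingering_source `"delta"` (default): the lingering rating derives
#'   from the participant's realized injection rate; `"transportation"`: it
#'   derives from the participant's transportation score alone, so condition
#'   carries no information beyond transportation.
#' @param n_oov Number of background tokens deliberately withheld from the
#'   embedding table, to exercise out-of-vocabulary handling (default 0).
#' @param seed Integer seed; identical configs yield bit-identical cohorts.
#' @return A `linger_config` list.
#' @export
synthetic_config <- function(n_participants_per_condition = 80,
                             conditions = list(
                               intact   = list(delta = 0.40, lambda = 0.05),
                               sentence = list(delta = 0.20, lambda = 0.05),
                               word     = list(delta = 0.05, lambda = 0.05)),
                             chain_length_mean = 60,
                             chain_length_dispersion = 40,
                             token_latency_mean_ms = 4888,
                             latency_shape = 12,
                             vocab_size_base = 500,
                             theme_cluster_size = 10,
                             n_background_clusters = 8,
                             embedding_dim = 50,
                             cluster_concentration = 2,
                             selfreport_noise_sd = 1,
                             delta_jitter = 0.05,
                             lingering_source = c("delta", "transportation"),
                             n_oov = 0,
                             seed = 1L) {
  lingering_source <- match.arg(lingering_source)
  stopifnot(n_participants_per_condition >= 1, length(conditions) >= 1,
            chain_length_mean >= 1, token_latency_mean_ms > 0,
            vocab_size_base >= 1, theme_cluster_size >= 1,
            embedding_dim >= 2, cluster_concentration > 0,
            delta_jitter >= 0, n_oov >= 0)
  for (nm in names(conditions)) {
    cc <- conditions[[nm]]
    if (is.null(cc$delta) || cc$delta < 0 || cc$delta > 1) {
      stop("condition ", sQuote(nm), ": delta must lie in [0, 1]",
           call. = FALSE)
    }
    if (is.null(cc$lambda) || cc$lambda < 0) {
      stop("condition ", sQuote(nm), ": lambda must be >= 0", call. = FALSE)
    }
  }
  structure(list(
    n_participants_per_condition = n_participants_per_condition,
    conditions = conditions,
    chain_length_mean = chain_length_mean,
    chain_length_dispersion = chain_length_dispersion,
    token_latency_mean_ms = token_latency_mean_ms,
    latency_shape = latency_shape,
    vocab_size_base = vocab_size_base,
    theme_cluster_size = theme_cluster_size,
    n_background_clusters = n_background_clusters,
    embedding_dim = embedding_dim,
    cluster_concentration = cluster_concentration,
    selfreport_noise_sd = selfreport_noise_sd,
    delta_jitter = delta_jitter,
    lingering_source = lingering_source,
    n_oov = n_oov,
    seed = as.integer(seed)), class = "linger_config")
}

#' Generate a clustered toy embedding table
#'
#' Each token's vector is its cluster center (a random unit vector unless
#' `centers` is supplied) plus isotropic Gaussian noise with expected norm
#' `1/concentration`, so the expected within-cluster cosine exceeds the
#' expected between-cluster cosine, with the margin growing in
#' `concentration`. A stand-in for pretrained distributional embeddings with
#' controlled semantic structure.
#'
#' @param vocab Character vector of unique tokens.
#' @param cluster_assignment Named character/integer vector mapping every
#'   token in `vocab` to exactly one cluster label.
#' @param dim Embedding dimension (>= 2).
#' @param concentration Positive real; larger means tighter clusters.
#' @param seed Integer seed.
#' @param centers Optional matrix of cluster centers (rows named by cluster
#'   label); random unit vectors when omitted.
#' @return Numeric matrix, one row per token (rownames = tokens).
#' @export
generate_embeddings <- function(vocab, cluster_assignment, dim,
                                concentration, seed, centers = NULL) {
  if (anyDuplicated(vocab)) stop("duplicate tokens in vocab", call. = FALSE)
  if (dim < 2) stop("embedding dim must be >= 2", call. = FALSE)
  if (!all(vocab %in% names(cluster_assignment))) {
    stop("every token must be assigned to exactly one cluster", call. = FALSE)
  }
  cl <- cluster_assignment[vocab]
  labels <- unique(cl)
  withr::with_seed(seed, {
    if (is.null(centers)) {
      centers <- matrix(stats::rnorm(length(labels) * dim), ncol = dim,
                        dimnames = list(labels, NULL))
      centers <- centers / sqrt(rowSums(centers^2))
    } else {
      stopifnot(ncol(centers) == dim, all(labels %in% rownames(centers)))
    }
    noise <- matrix(stats::rnorm(length(vocab) * dim,
                                 sd = 1 / (concentration * sqrt(dim))),
                    ncol = dim)
    emb <- centers[as.character(cl), , drop = FALSE] + noise
  })
  rownames(emb) <- vocab
  emb
}

#' Generate one free-association chain
#'
#' Pre-exposure chains are i.i.d. draws from the base token distribution.
#' In post-exposure chains the token at 1-based position `t` is drawn
#' uniformly from the theme set with probability `delta * exp(-lambda*(t-1))`
#' and from the base distribution otherwise, modelling theme material whose
#' intrusion rate decays as spontaneous thought drifts away from the
#' just-read text. Latencies are gamma-distributed around the mean.
#'
#' Consumes the current RNG stream; seed externally for reproducibility.
#'
#' @param phase `"pre"` or `"post"`.
#' @param delta Injection probability at position 1, in `[0,1]`.
#' @param lambda Decay rate per position, `>= 0`.
#' @param length Chain length in tokens (>= 1).
#' @param base_distribution Named numeric vector of token probabilities
#'   (must sum to 1).
#' @param theme_tokens Character vector of theme tokens (required when
#'   `phase = "post"` and `delta > 0`).
#' @param latency_mean_ms Mean per-token latency.
#' @param latency_shape Gamma shape for latencies.
#' @return List with `tokens` and `latencies_ms`.
#' @export
generate_chain <- function(phase = c("pre", "post"), delta = 0, lambda = 0,
                           length, base_distribution, theme_tokens = character(),
                           latency_mean_ms = 4888, latency_shape = 12) {
  phase <- match.arg(phase)
  if (delta < 0 || delta > 1) stop("delta must lie in [0, 1]", call. = FALSE)
  stopifnot(lambda >= 0, length >= 1)
  if (abs(sum(base_distribution) - 1) > 1e-8) {
    stop("base_distribution must sum to 1", call. = FALSE)
  }
  n <- as.integer(length)
  vocab <- names(base_distribution)
  tokens <- sample(vocab, n, replace = TRUE, prob = base_distribution)
  if (phase == "post" && delta > 0) {
    p_inj <- delta * exp(-lambda * (seq_len(n) - 1))
    inj <- stats::runif(n) < p_inj
    if (any(inj)) {
      if (!length(theme_tokens)) stop("theme_tokens required for injection",
                                      call. = FALSE)
      tokens[inj] <- sample(theme_tokens, sum(inj), replace = TRUE)
    }
  }
  lat <- round(stats::rgamma(n, shape = latency_shape,
                             rate = latency_shape / latency_mean_ms))
  list(tokens = tokens, latencies_ms = as.numeric(lat))
}

#' Expected number of injected theme tokens in a post chain
#'
#' Closed form for the injection model of [generate_chain()]:
#' `delta * (1 - exp(-lambda*L)) / (1 - exp(-lambda))` for `lambda > 0`
#' (geometric sum over positions), and `delta * L` for `lambda = 0`.
#'
#' @param delta,lambda,length Injection parameters as in [generate_chain()].
#' @return Expected injected-token count.
#' @export
expected_injected <- function(delta, lambda, length) {
  if (lambda == 0) return(delta * length)
  delta * (1 - exp(-lambda * length)) / (1 - exp(-lambda))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a full synthetic cohort
#'
#' Produces, per participant: a condition label; a realized injection rate
#' `delta_i` (condition delta plus bounded uniform jitter); pre and post
#' free-association chains; a 1-7 lingering rating; 13 transportation items
#' (1-7); 24 comprehension items (0/1); and up to 10 generated theme words
#' sampled from the theme cluster. Self-report variables are monotone
#' (linear-then-clamped) functions of `delta_i` plus Gaussian noise, so
#' conditions with stronger injection report more lingering, higher
#' transportation, and better comprehension. The base token distribution is
#' Zipfian over the background vocabulary; theme tokens enter chains only via
#' injection.
#'
#' Deterministic given the config seed.
#'
#' @param config A [synthetic_config()].
#' @return A `linger_cohort` list: `chains` (token-level tibble), `participants`
#'   (one row per participant with questionnaire list-columns), `embeddings`
#'   (matrix), and `ground_truth` (realized `delta_i`, theme tokens,
#'   deliberate OOV tokens).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "linger_config"))
  cfg <- config
  base_vocab <- sprintf("w%04d", seq_len(cfg$vocab_size_base))
  theme_tokens <- sprintf("theme%02d", seq_len(cfg$theme_cluster_size))
  vocab <- c(base_vocab, theme_tokens)
  cluster <- c(
    stats::setNames(sprintf("bg%02d",
      rep(seq_len(cfg$n_background_clusters),
          length.out = cfg$vocab_size_base)), base_vocab),
    stats::setNames(rep("theme", cfg$theme_cluster_size), theme_tokens))
  # Zipfian base frequencies over background tokens only
  base_probs <- stats::setNames((1 / seq_len(cfg$vocab_size_base)) /
                                  sum(1 / seq_len(cfg$vocab_size_base)),
                                base_vocab)
  # popularity weights for participant-generated theme words
  theme_pop <- (1 / seq_len(cfg$theme_cluster_size))

  embeddings <- generate_embeddings(vocab, cluster, cfg$embedding_dim,
                                    cfg$cluster_concentration,
                                    seed = stage_seed(cfg$seed, "embeddings"))
  oov_tokens <- character()
  if (cfg$n_oov > 0) {
    oov_tokens <- utils::tail(base_vocab, cfg$n_oov)
    embeddings <- embeddings[setdiff(rownames(embeddings), oov_tokens), ,
                             drop = FALSE]
  }

  withr::with_seed(stage_seed(cfg$seed, "cohort"), {
    rows_chain <- list(); rows_part <- list(); k <- 0L
    for (ci in seq_along(cfg$conditions)) {
      cond <- names(cfg$conditions)[ci]
      pars <- cfg$conditions[[ci]]
      for (j in seq_len(cfg$n_participants_per_condition)) {
        k <- k + 1L
        pid <- sprintf("p%03d", k)
        # jitter models between-participant variability in effect strength;
        # a condition with no effect (delta = 0) has none to vary, and
        # clamping jitter at 0 would otherwise leak signal into null cohorts
        delta_i <- if (pars$delta == 0) 0 else
          clamp(pars$delta +
                  stats::runif(1, -cfg$delta_jitter, cfg$delta_jitter), 0, 1)
        lens <- pmax(1L, stats::rnbinom(2, size = cfg$chain_length_dispersion,
                                        mu = cfg$chain_length_mean))
        pre <- generate_chain("pre", 0, 0, lens[1], base_probs,
                              latency_mean_ms = cfg$token_latency_mean_ms,
                              latency_shape = cfg$latency_shape)
        post <- generate_chain("post", delta_i, pars$lambda, lens[2],
                               base_probs, theme_tokens,
                               latency_mean_ms = cfg$token_latency_mean_ms,
                               latency_shape = cfg$latency_shape)
        # transportation: latent proportion tied to delta_i plus individual noise
        trans_p <- clamp(0.30 + 0.9 * delta_i + stats::rnorm(1, 0, 0.10), 0, 1)
        trans_items <- as.integer(clamp(round(1 + 6 * trans_p +
                                                stats::rnorm(13, 0, 0.8)), 1, 7))
        comp_p <- clamp(0.50 + 0.8 * delta_i + stats::rnorm(1, 0, 0.08),
                        0.05, 0.98)
        comp_items <- stats::rbinom(24, 1, comp_p)
        linger_latent <- switch(cfg$lingering_source,
          delta = 1.5 + 11 * delta_i,
          transportation = 1 + 6 * trans_p)
        lingering <- as.integer(clamp(round(linger_latent +
          stats::rnorm(1, 0, cfg$selfreport_noise_sd)), 1, 7))
        tw <- unique(sample(theme_tokens, 10, replace = TRUE,
                            prob = theme_pop))
        rows_part[[k]] <- tibble::tibble(
          participant_id = pid, condition = cond, delta = delta_i,
          lingering_rating = lingering,
          transportation = list(trans_items),
          comprehension = list(comp_items),
          theme_words = list(tw))
        rows_chain[[k]] <- tibble::tibble(
          participant_id = pid, condition = cond,
          phase = rep(c("pre", "post"), c(lens[1], lens[2])),
          position = c(seq_len(lens[1]), seq_len(lens[2])),
          token = c(pre$tokens, post$tokens),
          latency_ms = c(pre$latencies_ms, post$latencies_ms))
      }
    }
  })
  participants <- do.call(rbind, rows_part)
  chains <- do.call(rbind, rows_chain)
  structure(list(
    chains = chains,
    participants = participants[, setdiff(names(participants), "delta")],
    embeddings = embeddings,
    ground_truth = list(
      delta = participants[, c("participant_id", "condition", "delta")],
      theme_tokens = theme_tokens,
      oov_tokens = oov_tokens),
    config = cfg), class = "linger_cohort")
}

#' @export
print.linger_cohort <- function(x, ...) {
  cat("<linger_cohort> ", nrow(x$participants), " participants in ",
      length(unique(x$participants$condition)), " condition(s); ",
      nrow(x$chains), " tokens total\n", sep = "")
  invisible(x)
}

#' Generate a depth-of-processing word-list fixture
#'
#' Builds a list of `n_items` entries, each flagged italic/normal and
#' story/decoy, with exact counts `round(n * frac)`. The first 15 items are
#' always story words (mirroring a study design in which the opening items
#' establish the hidden narrative); decoys are pseudorandomly interspersed
#' thereafter. Italic flags are assigned only to story words.
#'
#' @param n_items Total list length (default 268).
#' @param frac_italic Fraction italicized (default 0.25; with `n_items = 268`
#'   this yields 67 italic items, ~25% of the list).
#' @param frac_decoy Fraction of decoy items (default 0.25).
#' @param seed Integer seed.
#' @return A tibble with columns `position`, `word`, `role` ("story"/"decoy"),
#'   `italic` (logical).
#' @export
generate_word_list <- function(n_items = 268, frac_italic = 0.25,
                               frac_decoy = 0.25, seed = 1L) {
  stopifnot(frac_italic >= 0, frac_italic <= 1,
            frac_decoy >= 0, frac_decoy <= 1, n_items >= 1)
  n_italic <- round(n_items * frac_italic)
  n_decoy <- round(n_items * frac_decoy)
  if (n_italic > n_items || n_decoy > n_items) {
    stop("flag counts exceed n_items", call. = FALSE)
  }
  n_story <- n_items - n_decoy
  if (n_italic > n_story) {
    stop("cannot italicize ", n_italic, " items: only ", n_story,
         " story words available as italic targets", call. = FALSE)
  }
  lead_in <- min(15L, n_story)
  withr::with_seed(seed, {
    role <- rep("story", n_items)
    if (n_decoy > 0) {
      pool <- setdiff(seq_len(n_items), seq_len(lead_in))
      role[sample(pool, n_decoy)] <- "decoy"
    }
    italic <- rep(FALSE, n_items)
    italic[sample(which(role == "story"), n_italic)] <- TRUE
  })
  word <- character(n_items)
  word[role == "story"] <- sprintf("story_%03d", seq_len(sum(role == "story")))
  word[role == "decoy"] <- sprintf("decoy_%03d", seq_len(sum(role == "decoy")))
  tibble::tibble(position = seq_len(n_items), word = word,
                 role = role, italic = italic)
}

#' Write a cohort's files to a directory
#'
#' Emits the chain TSV (`chains.tsv`), questionnaire CSV
#' (`questionnaires.csv`), and the toy embedding table in text format
#' (`embeddings.txt`: token followed by space-separated components, one token
#' per line).
#'
#' @param cohort A `linger_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "linger_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_chains(cohort$chains, file.path(dir, "chains.tsv"))
  write_questionnaires(cohort$participants, file.path(dir, "questionnaires.csv"))
  write_embeddings(cohort$embeddings, file.path(dir, "embeddings.txt"))
  invisible(dir)
}
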