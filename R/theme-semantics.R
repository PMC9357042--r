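#' Load a text-format word-embedding table
#'
#' Reads the standard text format used by pretrained distributional
#' embeddings (e.g. GloVe): one token per line, followed by
#' whitespace-separated decimal components. All lines must share one
#' dimension; non-numeric components, dimension mismatches, and zero vectors
#' are rejected with the offending line number.
#'
#' @param path Path to the embedding text file.
#' @param vocab_filter Optional character vector; when given, only these
#'   tokens are retained.
#' @return Numeric matrix, one row per token (rownames = tokens).
#' @export
load_embeddings <- function(path, vocab_filter = NULL) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty embedding file", call. = FALSE)
  parts <- strsplit(lines, "[ \t]+")
  dim0 <- length(parts[[1]]) - 1L
  if (dim0 < 1) stop("line 1: no vector components", call. = FALSE)
  out <- matrix(NA_real_, nrow = length(parts), ncol = dim0)
  toks <- character(length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) - 1L != dim0) {
      stop("line ", i, ": expected ", dim0, " components, found ",
           length(p) - 1L, call. = FALSE)
    }
    v <- suppressWarnings(as.numeric(p[-1]))
    if (anyNA(v)) stop("line ", i, ": non-numeric component", call. = FALSE)
    if (all(v == 0)) stop("line ", i, ": zero vector", call. = FALSE)
    toks[i] <- p[1]
    out[i, ] <- v
  }
  rownames(out) <- toks
  if (!is.null(vocab_filter)) {
    out <- out[rownames(out) %in% vocab_filter, , drop = FALSE]
  }
  out
}

#' Write an embedding table in text format
#'
#' One token per line followed by its space-separated components, printed
#' with enough digits that [load_embeddings()] round-trips the table exactly.
#'
#' @param embeddings Numeric matrix with token rownames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(embeddings, path) {
  stopifnot(is.matrix(embeddings), !is.null(rownames(embeddings)))
  lines <- vapply(seq_len(nrow(embeddings)), function(i) {
    paste(rownames(embeddings)[i],
          paste(sprintf("%.17g", embeddings[i, ]), collapse = " "))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Select the cohort's theme words
#'
#' Counts how often each normalized participant-generated theme word was
#' produced across the cohort and returns the `k` most frequent, after
#' removing (i) explicitly excluded tokens (cue words; proper nouns, which
#' lack the distributional properties of common nouns), (ii) tokens absent
#' from the embedding table, and (iii), when `leave_out` is set, the words
#' generated by that participant (so a participant's own productions never
#' define the themes they are scored against). Frequency ties break
#' alphabetically.
#'
#' @param participants Participants tibble with a `theme_words` list-column
#'   (or a `linger_cohort`).
#' @param embeddings Embedding matrix (token rownames).
#' @param k Number of theme words to keep (default 10).
#' @param exclusions Character vector of tokens to remove.
#' @param leave_out Optional participant id whose generated words are
#'   excluded from counting.
#' @return A `linger_themes` list: `tokens`, `vectors` (matrix), and
#'   `provenance` (frequency table, exclusions applied, `leave_out`,
#'   `short` flag when fewer than `k` candidates survive).
#' @export
select_theme_words <- function(participants, embeddings, k = 10,
                               exclusions = character(),
                               leave_out = NULL) {
  if (inherits(participants, "linger_cohort")) {
    participants <- participants$participants
  }
  keep <- rep(TRUE, nrow(participants))
  if (!is.null(leave_out)) keep <- participants$participant_id != leave_out
  words <- normalize_token(unlist(participants$theme_words[keep],
                                  use.names = FALSE))
  words <- words[nzchar(words)]
  freq <- sort(table(words), decreasing = TRUE)
  cand <- names(freq)
  cand <- setdiff(cand, normalize_token(exclusions))
  cand <- cand[cand %in% rownames(embeddings)]
  # order by frequency, ties alphabetical
  cand <- cand[order(-as.numeric(freq[cand]), cand)]
  short <- length(cand) < k
  if (short) {
    warning("only ", length(cand), " theme-word candidates survive ",
            "exclusion/OOV filtering (requested ", k, ")", call. = FALSE)
  }
  tokens <- utils::head(cand, k)
  structure(list(tokens = tokens,
                 vectors = embeddings[tokens, , drop = FALSE],
                 provenance = list(frequencies = freq,
                                   exclusions = exclusions,
                                   leave_out = leave_out,
                                   short = short)),
            class = "linger_themes")
}

#' @export
print.linger_themes <- function(x, ...) {
  cat("<linger_themes> ", length(x$tokens), " theme words: ",
      paste(x$tokens, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Theme similarity of one word vector
#'
#' The theme similarity of an associate with embedding vector `A` is the
#' maximal cosine similarity between `A` and any theme-word vector `B_i`:
#' `max_i (A . B_i) / (||A|| ||B_i||)`. Scale-invariant in `A`, and
#' unchanged by duplicated theme vectors.
#'
#' @param word_vector Numeric vector (nonzero).
#' @param themes A `linger_themes` set (non-empty).
#' @return A score in `[-1, 1]`.
#' @export
theme_similarity <- function(word_vector, themes) {
  stopifnot(inherits(themes, "linger_themes"), length(themes$tokens) >= 1)
  a <- as.numeric(word_vector)
  na <- sqrt(sum(a^2))
  if (na == 0) stop("zero word vector", call. = FALSE)
  B <- themes$vectors
  stopifnot(ncol(B) == length(a))
  nb <- sqrt(rowSums(B^2))
  max(drop(B %*% a) / (nb * na))
}

#' Mean theme similarity of a chain
#'
#' Scores every token occurrence in the chain (repeats are scored at every
#' occurrence) and averages. Tokens without an embedding entry are dropped
#' from both numerator and denominator. A chain with no in-vocabulary tokens
#' yields a missing value, flagged via `n_scored = 0`.
#'
#' @param tokens Character vector: the chain's tokens in order.
#' @param embeddings Embedding matrix.
#' @param themes A `linger_themes` set.
#' @return List with `mean` (NA when nothing scored) and `n_scored`.
#' @export
chain_theme_similarity <- function(tokens, embeddings, themes) {
  stopifnot(inherits(themes, "linger_themes"), length(themes$tokens) >= 1)
  iv <- tokens[tokens %in% rownames(embeddings)]
  if (!length(iv)) return(list(mean = NA_real_, n_scored = 0L))
  A <- embeddings[iv, , drop = FALSE]
  B <- themes$vectors
  sims <- (A %*% t(B)) / (sqrt(rowSums(A^2)) %o% sqrt(rowSums(B^2)))
  list(mean = mean(apply(sims, 1, max)), n_scored = length(iv))
}

#' Pre/post theme-similarity contrast for one participant
#'
#' Averages theme similarity over all in-vocabulary associates produced pre-
#' and post-exposure and reports the difference `post - pre`. A phase with no
#' scoreable tokens propagates a missing value.
#'
#' @param pre_tokens,post_tokens Token vectors of the participant's chains.
#' @param embeddings Embedding matrix.
#' @param themes A `linger_themes` set.
#' @return List with `pre_mean`, `post_mean`, `delta`.
#' @export
prepost_theme_delta <- function(pre_tokens, post_tokens, embeddings, themes) {
  pre <- chain_theme_similarity(pre_tokens, embeddings, themes)
  post <- chain_theme_similarity(post_tokens, embeddings, themes)
  list(pre_mean = pre$mean, post_mean = post$mean,
       delta = post$mean - pre$mean)
}

#' Per-participant theme-similarity table for a cohort
#'
#' Convenience wrapper applying [prepost_theme_delta()] to every participant
#' in a chains tibble.
#'
#' @param chains Chains tibble.
#' @param embeddings Embedding matrix.
#' @param themes A `linger_themes` set, or a named list of per-participant
#'   theme sets (e.g. from leave-one-out selection).
#' @return Tibble with `participant_id`, `condition`, `pre_mean`, `post_mean`,
#'   `delta`.
#' @export
cohort_theme_deltas <- function(chains, embeddings, themes) {
  pids <- unique(chains$participant_id)
  rows <- lapply(pids, function(p) {
    sub <- chains[chains$participant_id == p, ]
    th <- if (inherits(themes, "linger_themes")) themes else themes[[p]]
    d <- prepost_theme_delta(sub$token[sub$phase == "pre"],
                             sub$token[sub$phase == "post"],
                             embeddings, th)
    tibble::tibble(participant_id = p, condition = sub$condition[1],
                   pre_mean = d$pre_mean, post_mean = d$post_mean,
                   delta = d$delta)
  })
  do.call(rbind, rows)
}

paired_cohens_d <- function(pre, post, variant = c("dz", "dav")) {
  variant <- match.arg(variant)
  diff <- post - pre
  n <- length(diff)
  denom <- switch(variant,
    dz = stats::sd(diff),
    dav = (stats::sd(pre) + stats::sd(post)) / 2)
  # identical pre/post values give 0/0: no effect, not an undefined one
  d <- if (denom == 0 && mean(diff) == 0) 0 else mean(diff) / denom
  se <- sqrt(1 / n + d^2 / (2 * n))
  list(d = d, lower = d - 1.96 * se, upper = d + 1.96 * se, n = n)
}

#' Time-course of theme similarity in fixed-width associate bins
#'
#' Splits each chain into consecutive complete bins of `bin_width` associates
#' (bin `k` covers positions `(k-1)*bin_width + 1 ... k*bin_width`; partial
#' trailing bins are discarded). A participant contributes to bin `k` only if
#' both their pre and post chains have a complete bin `k`. Per bin, the
#' post-minus-pre difference in bin-mean theme similarity is summarized as a
#' paired Cohen's d with a 95% CI (`d +/- 1.96 * sqrt(1/n + d^2/(2n))`); a
#' bin is flagged significant when the CI excludes 0 (uncorrected). The bin
#' duration in seconds is `bin_width * latency_mean_ms / 1000` (with
#' defaults, 48.88 s, i.e. ~49 s per 10 associates).
#'
#' Two paired-d conventions are provided: `"dz"` (mean difference / SD of
#' differences, the default) and `"dav"` (mean difference / average of the
#' two phase SDs).
#'
#' @param chains Chains tibble.
#' @param embeddings Embedding matrix.
#' @param themes A `linger_themes` set (or named per-participant list).
#' @param bin_width Associates per bin (default 10).
#' @param latency_mean_ms Mean per-associate latency used to convert bins to
#'   seconds (default 4888).
#' @param d_variant `"dz"` or `"dav"`.
#' @return A `linger_timecourse` list: `bins` tibble (`bin`, `n`, `d`,
#'   `lower`, `upper`, `significant`), `bin_width`, `seconds_per_bin`.
#' @export
timecourse <- function(chains, embeddings, themes, bin_width = 10,
                       latency_mean_ms = 4888, d_variant = c("dz", "dav")) {
  d_variant <- match.arg(d_variant)
  stopifnot(bin_width >= 1)
  pids <- unique(chains$participant_id)
  # per participant & phase: bin means of theme similarity
  bin_means <- lapply(pids, function(p) {
    sub <- chains[chains$participant_id == p, ]
    th <- if (inherits(themes, "linger_themes")) themes else themes[[p]]
    lapply(c(pre = "pre", post = "post"), function(ph) {
      tok <- sub$token[sub$phase == ph][order(sub$position[sub$phase == ph])]
      n_bins <- length(tok) %/% bin_width
      if (n_bins == 0) return(numeric(0))
      vapply(seq_len(n_bins), function(k) {
        chunk <- tok[((k - 1) * bin_width + 1):(k * bin_width)]
        chain_theme_similarity(chunk, embeddings, th)$mean
      }, numeric(1))
    })
  })
  names(bin_means) <- pids
  max_bin <- max(vapply(bin_means, function(b)
    min(length(b$pre), length(b$post)), numeric(1)))
  if (max_bin < 1 ||
      sum(vapply(bin_means, function(b)
        length(b$pre) >= 1 && length(b$post) >= 1, logical(1))) == 0) {
    stop("no participant contributes a complete first bin", call. = FALSE)
  }
  rows <- lapply(seq_len(max_bin), function(k) {
    ok <- vapply(bin_means, function(b)
      length(b$pre) >= k && length(b$post) >= k &&
        !is.na(b$pre[k]) && !is.na(b$post[k]), logical(1))
    if (sum(ok) < 3) return(NULL)
    pre_k <- vapply(bin_means[ok], function(b) b$pre[k], numeric(1))
    post_k <- vapply(bin_means[ok], function(b) b$post[k], numeric(1))
    dd <- paired_cohens_d(pre_k, post_k, d_variant)
    tibble::tibble(bin = k, n = dd$n, d = dd$d, lower = dd$lower,
                   upper = dd$upper,
                   significant = dd$lower > 0 | dd$upper < 0)
  })
  bins <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(bins) || !nrow(bins)) {
    stop("no participant contributes a complete first bin", call. = FALSE)
  }
  structure(list(bins = bins, bin_width = bin_width,
                 seconds_per_bin = bin_width * latency_mean_ms / 1000,
                 d_variant = d_variant),
            class = "linger_timecourse")
}

#' @export
print.linger_timecourse <- function(x, ...) {
  cat("<linger_timecourse> ", nrow(x$bins), " bins of ", x$bin_width,
      " associates (", round(x$seconds_per_bin, 2), " s each); ",
      sum(x$bins$significant), " significant\n", sep = "")
  invisible(x)
}

#' Lingering duration from a time-course
#'
#' Counts the bins whose post-minus-pre Cohen's d confidence interval
#' excludes 0 (total count, not necessarily consecutive) and converts to
#' seconds via the time-course's bin duration.
#'
#' @param tc A `linger_timecourse`.
#' @return List with `n_significant_bins` and `seconds`.
#' @export
lingering_duration <- function(tc) {
  stopifnot(inherits(tc, "linger_timecourse"))
  n_sig <- sum(tc$bins$significant)
  list(n_significant_bins = n_sig, seconds = n_sig * tc$seconds_per_bin)
}
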