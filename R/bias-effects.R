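#' Word-level pre/post bias scores
#'
#' For every token that appears in any chain, computes the proportion of pre
#' chains containing it (`p_pre`), the proportion of post chains containing
#' it (`p_post`), the bias `p_post - p_pre`, and the odds ratio
#' `p_post / p_pre`. Presence semantics: a token counts once per chain no
#' matter how often it repeats; denominators are the number of chains per
#' phase. Odds ratios with `p_pre = 0` are flagged rather than smoothed (see
#' [odds_ratio()]).
#'
#' @param chains Chains tibble (columns `participant_id`, `phase`, `token`).
#' @return A `linger_bias` tibble: `token`, `p_pre`, `p_post`, `bias`,
#'   `odds_ratio` (NA when undefined), `or_flag` (`""`, `"> k"` lower bound,
#'   or `"undefined"`).
#' @export
bias_scores <- function(chains) {
  phase <- as.character(chains$phase)
  stopifnot(any(phase == "pre"), any(phase == "post"))
  chain_id <- paste(chains$participant_id, phase, sep = ":")
  pres <- unique(data.frame(chain_id = chain_id, phase = phase,
                            token = as.character(chains$token)))
  pres <- pres[nzchar(pres$token), ]
  n_pre <- length(unique(chain_id[phase == "pre"]))
  n_post <- length(unique(chain_id[phase == "post"]))
  tokens <- sort(unique(pres$token))
  c_pre <- table(factor(pres$token[pres$phase == "pre"], levels = tokens))
  c_post <- table(factor(pres$token[pres$phase == "post"], levels = tokens))
  p_pre <- as.numeric(c_pre) / n_pre
  p_post <- as.numeric(c_post) / n_post
  or <- mapply(odds_ratio, p_post, p_pre,
               MoreArgs = list(n_chains = n_post), SIMPLIFY = FALSE)
  out <- tibble::tibble(
    token = tokens, p_pre = p_pre, p_post = p_post,
    bias = p_post - p_pre,
    odds_ratio = vapply(or, function(o) o$ratio, numeric(1)),
    or_flag = vapply(or, function(o) o$flag, character(1)))
  class(out) <- c("linger_bias", class(out))
  out
}

#' Odds ratio of chain-presence proportions
#'
#' `p_post / p_pre`. When `p_pre = 0` but `p_post > 0` the ratio is
#' undefined; it is flagged with the lower bound `"> p_post * N"` (the value
#' the ratio would exceed had the word appeared in just one of `N` pre
#' chains). `0/0` is flagged `"undefined"`.
#'
#' @param p_post,p_pre Proportions in `[0, 1]`.
#' @param n_chains Number of chains per phase (used for the lower bound).
#' @return List with `ratio` (NA when undefined) and `flag`.
#' @export
odds_ratio <- function(p_post, p_pre, n_chains = NULL) {
  stopifnot(p_post >= 0, p_post <= 1, p_pre >= 0, p_pre <= 1)
  if (p_pre > 0) return(list(ratio = p_post / p_pre, flag = ""))
  if (p_post == 0) return(list(ratio = NA_real_, flag = "undefined"))
  bound <- if (is.null(n_chains)) "" else
    paste0("> ", format(p_post * n_chains, scientific = FALSE))
  list(ratio = NA_real_, flag = bound)
}

#' Display filter for a bias table
#'
#' Keeps tokens that are either prevalent (`max(p_pre, p_post) >=
#' min_prevalence`) or strongly biased (`|bias| >= min_abs_bias`) — the
#' legibility filter used when plotting word-level bias.
#'
#' @param table A `linger_bias` tibble.
#' @param min_prevalence Prevalence threshold (default 0.16).
#' @param min_abs_bias Absolute-bias threshold (default 0.10).
#' @return The filtered table.
#' @export
display_filter <- function(table, min_prevalence = 0.16,
                           min_abs_bias = 0.10) {
  keep <- pmax(table$p_pre, table$p_post) >= min_prevalence |
    abs(table$bias) >= min_abs_bias
  table[keep, ]
}

#' Rank-biserial correlation from a Mann-Whitney U statistic
#'
#' `r_rb = |1 - 2U / (n1 * n2)|`: the absolute difference between the
#' probability that a random observation from group 1 exceeds one from group
#' 2 and the converse.
#'
#' @param U Mann-Whitney U statistic (for group 1).
#' @param n1,n2 Group sizes.
#' @return Effect size in `[0, 1]`.
#' @export
rank_biserial <- function(U, n1, n2) {
  stopifnot(n1 >= 1, n2 >= 1, U >= 0, U <= n1 * n2)
  abs(1 - 2 * U / (n1 * n2))
}

#' Two-sided Mann-Whitney U test with rank-biserial effect size
#'
#' U is computed from rank sums with midrank ties; the two-sided p-value
#' uses the normal approximation with tie and continuity correction (via
#' [stats::wilcox.test()]). The rank-biserial effect size is
#' `|1 - 2U/(n1 n2)|`, with the direction (which group ranks higher)
#' reported alongside, since the magnitude alone is sign-blind.
#'
#' @param x,y Numeric/ordinal vectors for the two groups (non-empty).
#' @return List with `U`, `p`, `r_rank_biserial`, `direction`
#'   (`"x > y"`, `"y > x"`, or `"tie"`), `n1`, `n2`.
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty",
                                     call. = FALSE)
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                            correct = TRUE))
  U <- unname(wt$statistic)
  n1 <- length(x); n2 <- length(y)
  mr <- rank(c(x, y))
  mx <- mean(mr[seq_len(n1)]); my <- mean(mr[-seq_len(n1)])
  list(U = U, p = wt$p.value, r_rank_biserial = rank_biserial(U, n1, n2),
       direction = if (mx > my) "x > y" else if (my > mx) "y > x" else "tie",
       n1 = n1, n2 = n2)
}

#' Ranked epsilon-squared from a Kruskal-Wallis statistic
#'
#' `epsilon^2 = H * (n + 1) / (n^2 - 1)`, the rank-based analogue of the
#' proportion of variance explained by group.
#'
#' @param H Kruskal-Wallis chi-squared statistic.
#' @param n Total number of observations.
#' @return Effect size in `[0, 1]`.
#' @export
epsilon_squared_ranked <- function(H, n) {
  stopifnot(n >= 2, H >= 0)
  H * (n + 1) / (n^2 - 1)
}

#' Kruskal-Wallis rank-sum test with ranked epsilon-squared
#'
#' H (with midrank tie correction) and p come from [stats::kruskal.test()];
#' the effect size is `H (n+1)/(n^2-1)`.
#'
#' @param groups List of >= 2 numeric/ordinal vectors, each non-empty.
#' @return List with `H`, `df`, `p`, `epsilon_squared`, `n`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(lengths(groups) == 0)) {
    stop("every group must contain at least one observation", call. = FALSE)
  }
  n <- sum(lengths(groups))
  stopifnot(n >= 3)
  if (length(unique(unlist(groups))) == 1) {
    # all observations tied: no rank variance to partition
    return(list(H = 0, df = length(groups) - 1, p = 1,
                epsilon_squared = 0, n = n))
  }
  kt <- stats::kruskal.test(groups)
  H <- unname(kt$statistic)
  list(H = H, df = unname(kt$parameter), p = kt$p.value,
       epsilon_squared = epsilon_squared_ranked(H, n), n = n)
}

#' Pearson correlation with its t statistic
#'
#' Standard product-moment correlation; `t = r sqrt(df) / sqrt(1 - r^2)`
#' with `df = n - 2`.
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return List with `r`, `t`, `df`, `p`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), t = unname(ct$statistic),
       df = unname(ct$parameter), p = ct$p.value)
}
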