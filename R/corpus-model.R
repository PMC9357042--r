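#' Normalize a raw free-association entry
#'
#' Free-association entries arrive as raw typed text. Normalization lowercases
#' the entry, strips surrounding whitespace and punctuation, collapses internal
#' whitespace runs to a single hyphen (so multiword entries such as
#' "small town" become the single token "small-town"), and removes any
#' remaining characters outside `[a-z0-9-]`. An entry that normalizes to the
#' empty string (e.g. punctuation-only input) is droppable and is returned as
#' `""`.
#'
#' The function is total (never errors) and idempotent.
#'
#' @param raw Character vector of raw entries.
#' @return Character vector of normalized tokens; `""` marks a droppable entry.
#' @examples
#' normalize_token(c("Murder!", "  small town ", "..."))
#' @export
normalize_token <- function(raw) {
  x <- tolower(as.character(raw))
  x <- trimws(x)
  x <- gsub("\\s+", "-", x)
  x <- gsub("[^a-z0-9-]", "", x)
  # hyphens introduced by collapsing may now sit at the edges
  x <- gsub("^-+|-+$", "", x)
  x <- gsub("-{2,}", "-", x)
  x[is.na(x)] <- ""
  x
}

chain_tsv_columns <- c("participant_id", "condition", "phase",
                       "position", "token", "latency_ms")

#' Read free-association chains from TSV
#'
#' The chain format is tab-separated UTF-8 with the exact header
#' `participant_id, condition, phase, position, token, latency_ms`, one row
#' per produced associate. Within each (participant, phase) chain, positions
#' must run consecutively from 1; the phase must be `"pre"` or `"post"`.
#' Violations are rejected with the offending row number.
#'
#' @param path Path to a chain TSV file.
#' @return A tibble with the six chain columns (one row per token).
#' @seealso [write_chains()]
#' @export
read_chains <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", colClasses = "character",
                           check.names = FALSE, quote = "")
  if (!identical(names(raw), chain_tsv_columns)) {
    stop("chain file must have header exactly: ",
         paste(chain_tsv_columns, collapse = ", "), call. = FALSE)
  }
  raw$position <- suppressWarnings(as.integer(raw$position))
  raw$latency_ms <- suppressWarnings(as.numeric(raw$latency_ms))
  bad_phase <- which(!raw$phase %in% c("pre", "post"))
  if (length(bad_phase)) {
    stop("unknown phase ", sQuote(raw$phase[bad_phase[1]]),
         " at row ", bad_phase[1], call. = FALSE)
  }
  if (anyNA(raw$position)) {
    stop("non-integer position at row ", which(is.na(raw$position))[1],
         call. = FALSE)
  }
  key <- paste(raw$participant_id, raw$phase, sep = "\r")
  for (k in unique(key)) {
    idx <- which(key == k)
    expected <- seq_along(idx)
    off <- which(raw$position[idx] != expected)
    if (length(off)) {
      stop("non-consecutive position at row ", idx[off[1]],
           " (expected ", expected[off[1]], ", got ",
           raw$position[idx][off[1]], ")", call. = FALSE)
    }
  }
  tibble::as_tibble(raw)
}

#' Write free-association chains to TSV
#'
#' Inverse of [read_chains()]: writing then reading reproduces the chains
#' exactly (latencies are stored as integers).
#'
#' @param chains A chains tibble (see [read_chains()] for columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chains <- function(chains, path) {
  stopifnot(all(chain_tsv_columns %in% names(chains)))
  out <- as.data.frame(chains)[, chain_tsv_columns]
  out$latency_ms <- format(out$latency_ms, scientific = FALSE, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Build a raw-count document-term matrix from chains
#'
#' Each chain (one participant-phase) becomes one row; columns are the sorted
#' union of unique tokens over all supplied chains; values are raw
#' within-chain counts. Each participant must contribute exactly one `pre` and
#' one `post` chain. Rows are ordered by participant, `pre` before `post`.
#'
#' @param chains A chains tibble (columns `participant_id`, `phase`, `token`,
#'   optionally others; see [read_chains()]).
#' @return A `linger_dtm` object: list with `values` (numeric matrix),
#'   `participant_id` and `phase` (row metadata), `vocabulary`, and the
#'   logical flag `scaled` (`FALSE` here).
#' @export
build_dtm <- function(chains) {
  pid <- as.character(chains$participant_id)
  phase <- as.character(chains$phase)
  tok <- as.character(chains$token)
  chk <- tapply(phase, pid, function(p) {
    length(unique(p)) == 2 && all(sort(unique(p)) == c("post", "pre"))
  })
  if (!all(chk)) {
    stop("each participant needs exactly one pre and one post chain; ",
         "offending participant(s): ",
         paste(names(chk)[!chk], collapse = ", "), call. = FALSE)
  }
  participants <- sort(unique(pid))
  keep <- nzchar(tok)  # "" marks a droppable entry / empty-chain placeholder
  vocab <- sort(unique(tok[keep]))
  row_pid <- rep(participants, each = 2L)
  row_phase <- rep(c("pre", "post"), times = length(participants))
  values <- matrix(0, nrow = length(row_pid), ncol = length(vocab),
                   dimnames = list(paste(row_pid, row_phase, sep = ":"), vocab))
  if (any(keep)) {
    rkey <- paste(pid[keep], phase[keep], sep = ":")
    counts <- table(rkey, tok[keep])
    values[rownames(counts), colnames(counts)] <- as.numeric(counts)
  }
  structure(list(values = values, participant_id = row_pid,
                 phase = row_phase, vocabulary = vocab, scaled = FALSE),
            class = "linger_dtm")
}

#' @export
print.linger_dtm <- function(x, ...) {
  cat("<linger_dtm> ", nrow(x$values), " chains (",
      length(unique(x$participant_id)), " participants) x ",
      length(x$vocabulary), " tokens; ",
      if (x$scaled) "scaled" else "raw counts", "\n", sep = "")
  invisible(x)
}

#' Scale a document-term matrix within participant
#'
#' Two-step rescaling of raw counts: (1) each column (word) is mean-centered
#' within participant, so a participant's pre/post pair becomes
#' \eqn{\pm(post-pre)/2} and sums to zero; (2) each column is divided by the
#' across-chain standard deviation of the centered column, using the
#' population (n) convention. Columns with zero variance (identical pre and
#' post counts for every participant) carry no pre/post signal and are left
#' as all zeros rather than producing NaN.
#'
#' Downstream linear classification is invariant to the n vs. n-1 choice up
#' to a positive per-column rescale. Applying the scaling twice is rejected.
#'
#' @param dtm A raw-count `linger_dtm` from [build_dtm()].
#' @return A `linger_dtm` with `scaled = TRUE`.
#' @export
scale_dtm <- function(dtm) {
  stopifnot(inherits(dtm, "linger_dtm"))
  if (isTRUE(dtm$scaled)) stop("matrix is already scaled", call. = FALSE)
  v <- dtm$values
  for (p in unique(dtm$participant_id)) {
    rows <- which(dtm$participant_id == p)
    v[rows, ] <- sweep(v[rows, , drop = FALSE], 2, colMeans(v[rows, , drop = FALSE]))
  }
  n <- nrow(v)
  sd_pop <- sqrt(colSums(v^2) / n - (colSums(v) / n)^2)
  keep <- sd_pop > 0
  v[, keep] <- sweep(v[, keep, drop = FALSE], 2, sd_pop[keep], "/")
  v[, !keep] <- 0
  dtm$values <- v
  dtm$scaled <- TRUE
  dtm
}

#' Score a questionnaire as a proportion of the maximum
#'
#' Items are summed and divided by the maximum achievable total
#' (`length(items) * scale_max`), so 1 is the highest achievable score. Used
#' both for 1-7 transportation ratings (`scale_max = 7`) and 0/1 comprehension
#' correctness (`scale_max = 1`, giving proportion correct).
#'
#' @param items Numeric vector of item scores, each in `[0, scale_max]`.
#' @param scale_max Maximum possible single-item score.
#' @return A proportion in `[0, 1]`.
#' @examples
#' score_questionnaire(rep(7, 13), 7)  # 1
#' score_questionnaire(rep(1, 13), 7)  # 13/91
#' @export
score_questionnaire <- function(items, scale_max) {
  stopifnot(length(items) >= 1, scale_max > 0)
  if (any(is.na(items)) || any(items < 0) || any(items > scale_max)) {
    stop("item scores must lie in [0, ", scale_max, "]", call. = FALSE)
  }
  sum(items) / (length(items) * scale_max)
}

#' Write per-participant questionnaire data to CSV
#'
#' One row per participant: id, condition, lingering rating, the 13
#' transportation items (`transport_01`..`transport_13`), the 24 comprehension
#' items (`comp_01`..`comp_24`), and the generated theme words joined by `;`.
#'
#' @param participants The `participants` tibble of a [generate_cohort()]
#'   cohort.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_questionnaires <- function(participants, path) {
  tw <- vapply(participants$theme_words, paste, "", collapse = ";")
  tr <- do.call(rbind, participants$transportation)
  colnames(tr) <- sprintf("transport_%02d", seq_len(ncol(tr)))
  co <- do.call(rbind, participants$comprehension)
  colnames(co) <- sprintf("comp_%02d", seq_len(ncol(co)))
  out <- data.frame(participant_id = participants$participant_id,
                    condition = participants$condition,
                    lingering_rating = participants$lingering_rating,
                    tr, co, theme_words = tw, check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read per-participant questionnaire data written by [write_questionnaires()]
#'
#' @param path Path to the questionnaire CSV.
#' @return A participants tibble with list-columns `transportation`,
#'   `comprehension`, and `theme_words`.
#' @export
read_questionnaires <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  tr_cols <- grep("^transport_", names(raw))
  co_cols <- grep("^comp_", names(raw))
  tibble::tibble(
    participant_id = raw$participant_id,
    condition = raw$condition,
    lingering_rating = as.integer(raw$lingering_rating),
    transportation = lapply(seq_len(nrow(raw)), function(i)
      as.integer(unlist(raw[i, tr_cols], use.names = FALSE))),
    comprehension = lapply(seq_len(nrow(raw)), function(i)
      as.integer(unlist(raw[i, co_cols], use.names = FALSE))),
    theme_words = lapply(strsplit(raw$theme_words, ";", fixed = TRUE),
                         function(w) w[nzchar(w)])
  )
}
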