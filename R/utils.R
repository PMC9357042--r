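#' Derive a sub-stage seed from a global seed
#'
#' Deterministically hashes (global seed, stage name) into a positive 32-bit
#' integer, so each pipeline stage gets its own reproducible random stream
#' and can be re-run in isolation with identical randomness.
#'
#' @param seed Integer global seed.
#' @param stage Stage name (character scalar).
#' @return A positive integer below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(stage)) h <- (h * 131 + code) %% m
  as.integer(h + 1)
}
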