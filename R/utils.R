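#' Round half away from zero
#'
#' Event sample indices are remapped across sampling rates with
#' round-half-away-from-zero semantics (so 511.5 -> 512, -0.5 -> -1),
#' unlike [base::round()]'s banker's rounding.
#'
#' @param x Numeric vector.
#' @return Integer-valued numeric vector.
#' @keywords internal
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Derive a named substream seed from a global seed
#'
#' All randomness in a pipeline run flows from one global seed; each stage
#' draws its own substream seed deterministically so stages can be re-run
#' in isolation. Result always fits in a 32-bit integer.
#'
#' @param seed Global integer seed.
#' @param stream Character stage name.
#' @return An integer seed.
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# latent log-association-strength predictor: log(AS) for AS >= 1 and a
# finite floor for AS = 0 (unrelated pairs behave as if weakly associable,
# not as log(0) = -Inf). Used by the response model and amplitude rules.
latent_log_as <- function(as_score, zero_value = -2) {
  ifelse(as_score >= 1, log(as_score), zero_value)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
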