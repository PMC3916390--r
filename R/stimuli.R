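#' Generate a semantic-priming stimulus list
#'
#' Builds a word-pair list with the three-block association-strength (AS)
#' composition used in free-association-norm priming designs: a block of
#' unrelated pairs (AS = 0), a block of top associates with AS drawn
#' uniformly from a high range, and a middle block whose log(AS) is uniform
#' between log(1) and log of the lower edge of the top range. AS is the
#' count (0-100) of norm-study participants producing the target as first
#' associate of the prime. Lexical covariates (target length 4-6 letters,
#' in-degree >= 5) are attached so downstream code can exercise
#' covariate-bearing item tables; no linguistic content is modelled.
#'
#' @param n_total Total number of word-pairs (default 800).
#' @param n_zero Number of unrelated pairs with AS = 0 (default 100).
#' @param n_top Number of top-associate pairs (default 100).
#' @param top_range Integer range the top block's AS is drawn from
#'   (default `c(69, 95)`).
#' @param seed Integer seed; the list is deterministic given the seed.
#' @return A `data.frame` with columns `pair_id`, `as_score`,
#'   `target_length`, `in_degree`.
#' @export
#' @examples
#' pairs <- generate_stimulus_list(seed = 1)
#' table(cut(pairs$as_score, c(-1, 0, 68, 100)))
generate_stimulus_list <- function(n_total = 800, n_zero = 100, n_top = 100,
                                   top_range = c(69, 95), seed = NULL) {
  if (n_zero < 0 || n_top < 0 || n_total < 1)
    stopf("generate_stimulus_list: counts must be non-negative and n_total >= 1")
  if (n_zero + n_top > n_total)
    stopf("generate_stimulus_list: n_zero + n_top (%d) exceeds n_total (%d)",
          n_zero + n_top, n_total)
  if (length(top_range) != 2 || top_range[1] > top_range[2] ||
      top_range[1] < 1 || top_range[2] > 100)
    stopf("generate_stimulus_list: top_range must be an increasing pair within 1..100")

  if (!is.null(seed)) set.seed(seed)
  n_mid <- n_total - n_zero - n_top

  as_zero <- rep(0L, n_zero)
  as_top <- if (n_top > 0) {
    sample(seq(top_range[1], top_range[2]), n_top, replace = TRUE)
  } else integer(0)
  as_mid <- if (n_mid > 0) {
    # log(AS) uniform on [log 1, log(min(top_range))], rounded to counts
    u <- stats::runif(n_mid, 0, log(top_range[1]))
    pmin(pmax(round_half_away(exp(u)), 1L), top_range[1] - 1L)
  } else integer(0)

  as_score <- as.integer(c(as_zero, as_mid, as_top))
  n <- length(as_score)
  data.frame(
    pair_id = sprintf("pair%04d", seq_len(n)),
    as_score = as_score,
    target_length = sample(4:6, n, replace = TRUE),
    in_degree = 5L + stats::rpois(n, lambda = 12),
    stringsAsFactors = FALSE
  )
}
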