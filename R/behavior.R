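#' Default per-subject behavioural generative parameters
#'
#' Each subject carries the generative analogue of the random-effect
#' structure used in the analysis models: a subject-specific RT intercept
#' and log-AS slope, a trial-level RT noise SD, the logistic parameters
#' mapping latent log-AS to P("related"), and a no-response (miss) rate.
#' Population defaults are calibrated so that 8-way AS bins reproduce the
#' canonical speeded-task pattern: bin-mean RT rising from roughly 0.49 s
#' (strong associates) to 0.67 s (unrelated), response ratio falling from
#' ~0.98 to ~0.26, with ~3% misses (speeded) or ~0.6% (delayed).
#'
#' @param n_subjects Number of subjects (default 10).
#' @param condition `"speeded"` or `"delayed"`; sets the default miss rate.
#' @param seed Integer seed.
#' @param rt_intercept_mean,rt_intercept_sd Population intercept (s).
#' @param rt_slope_mean,rt_slope_sd Population log-AS slope (s per log-AS
#'   unit; negative = faster for strong associates).
#' @param rt_noise_sd Trial-level RT noise SD (s).
#' @param bias_midpoint,bias_slope Logistic response model parameters on
#'   the latent log-AS scale.
#' @param miss_rate Probability of a no-response trial; `NULL` picks the
#'   condition default (0.03 speeded, 0.006 delayed).
#' @return A `data.frame`, one row per subject.
#' @export
subject_profiles <- function(n_subjects = 10,
                             condition = c("speeded", "delayed"),
                             seed = NULL,
                             rt_intercept_mean = 0.67, rt_intercept_sd = 0.05,
                             rt_slope_mean = -0.04, rt_slope_sd = 0.008,
                             rt_noise_sd = 0.12,
                             bias_midpoint = -0.95, bias_slope = 1.0,
                             miss_rate = NULL) {
  condition <- match.arg(condition)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(miss_rate)) miss_rate <- if (condition == "speeded") 0.03 else 0.006
  slope <- pmin(rt_slope_mean + stats::rnorm(n_subjects, 0, rt_slope_sd), -0.005)
  data.frame(
    subject_id = sprintf("S%02d", seq_len(n_subjects)),
    rt_intercept = rt_intercept_mean + stats::rnorm(n_subjects, 0, rt_intercept_sd),
    rt_logas_slope = slope,
    rt_noise_sd = rt_noise_sd,
    bias_midpoint = bias_midpoint + stats::rnorm(n_subjects, 0, 0.15),
    bias_slope = bias_slope,
    miss_rate = miss_rate,
    stringsAsFactors = FALSE
  )
}

#' Simulate behavioural trials (RT + binary relatedness judgement)
#'
#' Every word-pair is presented once per subject. In the speeded condition
#' RT follows `rt_intercept + rt_logas_slope * log(max(AS, 1)) + noise`,
#' clipped to the response deadline; in the delayed condition RT is drawn
#' around 1.26 s from target onset, independent of AS (the response is cued
#' 1 s after target onset and the decision is prepared in advance). The
#' binary related/unrelated judgement follows a logistic in the latent
#' log-AS predictor, which assigns AS = 0 pairs a finite floor below
#' log(1) so the unrelated block yields a distinctly lower response ratio
#' than AS = 1 pairs. Misses (no response before the deadline) are flagged.
#'
#' @param pairs Stimulus list from [generate_stimulus_list()].
#' @param profiles Subject table from [subject_profiles()].
#' @param condition `"speeded"` or `"delayed"`.
#' @param seed Integer seed.
#' @param deadline Response deadline in seconds from the moment responses
#'   are allowed (target onset when speeded; cue onset when delayed).
#' @param delayed_rt_mean,delayed_rt_sd Delayed-condition RT distribution
#'   (seconds from target onset).
#' @param zero_as_latent Latent log-AS value used for AS = 0 pairs in the
#'   response model.
#' @return A `data.frame` of trial records: `trial_id`, `subject_id`,
#'   `pair_id`, `as_score`, `condition`, `rt_s` (seconds from target onset;
#'   `NA` when missed), `response` ("related"/"unrelated"; `NA` when
#'   missed), `missed`.
#' @export
simulate_behavior <- function(pairs, profiles,
                              condition = c("speeded", "delayed"),
                              seed = NULL, deadline = 1.0,
                              delayed_rt_mean = 1.26, delayed_rt_sd = 0.13,
                              zero_as_latent = -2) {
  condition <- match.arg(condition)
  if (!is.null(seed)) set.seed(seed)

  out <- vector("list", nrow(profiles))
  for (i in seq_len(nrow(profiles))) {
    p <- profiles[i, ]
    n <- nrow(pairs)
    if (condition == "speeded") {
      rt <- p$rt_intercept + p$rt_logas_slope * log(pmax(pairs$as_score, 1)) +
        stats::rnorm(n, 0, p$rt_noise_sd)
      rt <- pmin(pmax(rt, 0.15), deadline)
    } else {
      # responses occur after the cue at 1 s; RT measured from target onset
      rt <- stats::rnorm(n, delayed_rt_mean, delayed_rt_sd)
      rt <- pmin(pmax(rt, 1.02), 1 + deadline)
    }
    x <- latent_log_as(pairs$as_score, zero_as_latent)
    p_rel <- stats::plogis(p$bias_slope * (x - p$bias_midpoint))
    related <- stats::runif(n) < p_rel
    missed <- stats::runif(n) < p$miss_rate
    out[[i]] <- data.frame(
      subject_id = p$subject_id,
      pair_id = pairs$pair_id,
      as_score = pairs$as_score,
      condition = condition,
      rt_s = ifelse(missed, NA_real_, rt),
      response = ifelse(missed, NA_character_,
                        ifelse(related, "related", "unrelated")),
      missed = missed,
      stringsAsFactors = FALSE
    )
  }
  trials <- do.call(rbind, out)
  trials$trial_id <- sprintf("%s_%s_%s", substr(condition, 1, 3),
                             trials$subject_id, trials$pair_id)
  rownames(trials) <- NULL
  trials[, c("trial_id", "subject_id", "pair_id", "as_score", "condition",
             "rt_s", "response", "missed")]
}

#' Write a behavioural trial table as TSV
#' @param trials Trial table from [simulate_behavior()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_behavior_tsv <- function(trials, path) {
  utils::write.table(trials, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
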