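#' Trial matching score
#'
#' L1 sum of the discrepancies of a trial's RT and estimated P3 latency
#' from their targets: `w_rt * |rt - rt_target| + w_p3 * |p3 - p3_target|`
#' (seconds). Zero iff both match exactly; symmetric in the two terms at
#' equal weights. Both targets default to 0.65 s, late enough that a P3
#' placed there no longer overlaps the N400 analysis window.
#'
#' @param trial_rt,trial_p3 Trial RT and estimated P3 latency (s).
#' @param rt_target,p3_target Score targets (s, default 0.65).
#' @param weights Length-2 weights for the RT and P3 terms.
#' @return Numeric score(s).
#' @export
match_score <- function(trial_rt, trial_p3, rt_target = 0.65,
                        p3_target = 0.65, weights = c(1, 1)) {
  weights[1] * abs(trial_rt - rt_target) + weights[2] * abs(trial_p3 - p3_target)
}

#' Build P3-latency/AS "competition" trial groups
#'
#' Four groups designed so N400 and P3-latency effects pull in opposite
#' directions: group 1 = speeded trials with low AS (expected more
#' negative N400) but short estimated P3 latency; group 2 = speeded trials
#' with high AS but long latency; groups 3 and 4 = the delayed-condition
#' trials matching groups 1 and 2 on (subject, word-pair). Subject-pair
#' combinations unavailable in the delayed condition (e.g. rejected
#' no-response trials) are removed from all groups, and equal group sizes
#' are then enforced by seeded random discard from the larger selection,
#' so all four final groups have identical size.
#'
#' @param speeded_trials Speeded trial table carrying `latency_s` (join of
#'   behaviour and a `latency_table`).
#' @param delayed_trials Delayed trial table (post-rejection).
#' @param as_low_max Maximum AS of the low-AS selection (default 1).
#' @param as_high_min Minimum AS of the high-AS selection (default 18).
#' @param p3_short_max Maximum latency of the short-latency selection (s).
#' @param p3_long_min Minimum latency of the long-latency selection (s).
#' @param seed Seed for the equalizing random discard.
#' @return A `data.frame` (`group` 1..4, `subject_id`, `pair_id`,
#'   `trial_id`) with equal group sizes.
#' @export
build_competition_groups <- function(speeded_trials, delayed_trials,
                                     as_low_max = 1, as_high_min = 18,
                                     p3_short_max = 0.5, p3_long_min = 0.6,
                                     seed = NULL) {
  if (is.null(speeded_trials$latency_s))
    stopf("build_competition_groups: speeded trials lack a latency_s column")
  if (!is.null(seed)) set.seed(seed)
  key <- function(d) paste(d$subject_id, d$pair_id, sep = "\r")
  del_keys <- key(delayed_trials)

  sel1 <- speeded_trials[speeded_trials$as_score <= as_low_max &
                           !is.na(speeded_trials$latency_s) &
                           speeded_trials$latency_s <= p3_short_max, ]
  sel2 <- speeded_trials[speeded_trials$as_score >= as_high_min &
                           !is.na(speeded_trials$latency_s) &
                           speeded_trials$latency_s >= p3_long_min, ]
  if (nrow(sel1) == 0)
    stopf("build_competition_groups: no trials with AS <= %g and latency <= %g s",
          as_low_max, p3_short_max)
  if (nrow(sel2) == 0)
    stopf("build_competition_groups: no trials with AS >= %g and latency >= %g s",
          as_high_min, p3_long_min)
  # combinations absent in the delayed condition are removed from all groups
  sel1 <- sel1[key(sel1) %in% del_keys, ]
  sel2 <- sel2[key(sel2) %in% del_keys, ]
  if (nrow(sel1) == 0 || nrow(sel2) == 0)
    stopf("build_competition_groups: selection emptied by delayed-condition matching")
  n <- min(nrow(sel1), nrow(sel2))
  thin <- function(d) d[sort(sample(nrow(d), n)), ]
  sel1 <- thin(sel1); sel2 <- thin(sel2)
  partner <- function(sel) {
    m <- delayed_trials[match(key(sel), del_keys), ]
    m
  }
  sel3 <- partner(sel1); sel4 <- partner(sel2)
  mk <- function(d, g) data.frame(group = g, subject_id = d$subject_id,
                                  pair_id = d$pair_id, trial_id = d$trial_id,
                                  stringsAsFactors = FALSE)
  out <- rbind(mk(sel1, 1L), mk(sel2, 2L), mk(sel3, 3L), mk(sel4, 4L))
  rownames(out) <- NULL
  out
}

#' Build fixed-latency matched low-/high-AS groups
#'
#' Per subject: among low-AS trials (AS <= `as_low_max`), select the
#' `n_per_subject` trials with the lowest [match_score()] against the
#' fixed targets (RT and P3 latency both 0.65 s by default), ties broken
#' by trial id. Then, walking the selected low-AS trials in ascending
#' score order, greedily pair each with the not-yet-taken high-AS trial
#' (AS >= `as_high_min`, same subject) minimizing the score with targets
#' set to that low-AS trial's own RT and latency (1:1 matching without
#' replacement, ties by trial id). The result is two groups with near
#' identical RT and P3-latency distributions, differing in AS — an
#' N400 contrast uncontaminated by P3-latency differences.
#'
#' @param speeded_trials Speeded trial table carrying `latency_s`.
#' @param as_low_max,as_high_min AS cutoffs (defaults 1 and 18).
#' @param n_per_subject Trials selected per subject (default 75).
#' @param rt_target,p3_target Fixed score targets in seconds (0.65).
#' @param weights Score weights, see [match_score()].
#' @return A `data.frame` with columns `group` ("lowAS"/"highAS"),
#'   `subject_id`, `pair_id`, `trial_id`, `partner_trial_id`, `score`.
#' @export
build_fixed_latency_groups <- function(speeded_trials, as_low_max = 1,
                                       as_high_min = 18, n_per_subject = 75,
                                       rt_target = 0.65, p3_target = 0.65,
                                       weights = c(1, 1)) {
  if (is.null(speeded_trials$latency_s))
    stopf("build_fixed_latency_groups: trials lack a latency_s column")
  tr <- speeded_trials[!is.na(speeded_trials$latency_s) &
                         !is.na(speeded_trials$rt_s), ]
  subjects <- unique(tr$subject_id)
  shortfall <- character(0)
  rows <- list()
  for (s in subjects) {
    low <- tr[tr$subject_id == s & tr$as_score <= as_low_max, ]
    high <- tr[tr$subject_id == s & tr$as_score >= as_high_min, ]
    if (nrow(low) < n_per_subject || nrow(high) < n_per_subject) {
      shortfall <- c(shortfall, sprintf(
        "%s: %d low-AS / %d high-AS eligible (need %d)",
        s, nrow(low), nrow(high), n_per_subject))
      next
    }
    low$sc <- match_score(low$rt_s, low$latency_s, rt_target, p3_target,
                          weights)
    low <- low[order(low$sc, low$trial_id), ][seq_len(n_per_subject), ]
    taken <- logical(nrow(high))
    for (i in seq_len(nrow(low))) {
      psc <- match_score(high$rt_s, high$latency_s,
                         rt_target = low$rt_s[i],
                         p3_target = low$latency_s[i], weights = weights)
      psc[taken] <- Inf
      ord <- order(psc, high$trial_id)
      j <- ord[1]
      taken[j] <- TRUE
      rows[[length(rows) + 1L]] <- data.frame(
        group = c("lowAS", "highAS"), subject_id = s,
        pair_id = c(low$pair_id[i], high$pair_id[j]),
        trial_id = c(low$trial_id[i], high$trial_id[j]),
        partner_trial_id = c(high$trial_id[j], low$trial_id[i]),
        score = c(low$sc[i], psc[j]), stringsAsFactors = FALSE)
    }
  }
  if (length(shortfall))
    stopf("build_fixed_latency_groups: insufficient eligible trials:\n  %s",
          paste(shortfall, collapse = "\n  "))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Contrast two trial groups on a windowed channel amplitude
#'
#' Computes per-trial mean amplitudes (default Pz, 400-500 ms), the two
#' group means and their difference (first minus second group), and tests
#' the difference with the standard mixed model: amplitude ~ group coding
#' (+1 first group, -1 second) with by-subject intercept+slope and
#' by-word-pair intercept random effects.
#'
#' @param epochs An `epoch_set` containing the groups' trials.
#' @param assignment Group table (from either group builder, or any
#'   `data.frame` with `group`, `trial_id`).
#' @param groups Length-2 vector naming the two groups to contrast
#'   (default the first two distinct values in order of appearance).
#' @param channel,window Amplitude extraction, see [mean_amplitude()].
#' @return A list: `group_means` (named), `difference`, `lme`
#'   (an `lme_result`), `n` per group.
#' @export
contrast_groups <- function(epochs, assignment, groups = NULL,
                            channel = "Pz", window = c(0.4, 0.5)) {
  if (is.null(groups)) groups <- unique(assignment$group)[1:2]
  a <- assignment[assignment$group %in% groups, ]
  idx <- match(a$trial_id, epochs$trials$trial_id)
  if (any(is.na(idx)))
    stopf("contrast_groups: %d group trials missing from the epoch set",
          sum(is.na(idx)))
  amp_all <- mean_amplitude(epochs, channel, window)
  d <- data.frame(amplitude = amp_all[idx],
                  coding = ifelse(a$group == groups[1], 1, -1),
                  subject_id = epochs$trials$subject_id[idx],
                  pair_id = epochs$trials$pair_id[idx],
                  stringsAsFactors = FALSE)
  means <- tapply(d$amplitude, factor(a$group, levels = groups), mean)
  res <- fit_lme(d, dependent = "amplitude", fixed = "coding")
  list(group_means = means, difference = unname(means[1] - means[2]),
       lme = res, n = table(factor(a$group, levels = groups)))
}

#' Export a group assignment as TSV
#' @param assignment Group table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_groups_tsv <- function(assignment, path) {
  utils::write.table(assignment, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
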