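#' Configuration for iterative Woody P3-latency estimation
#'
#' @param prefilter_band Band-pass (Hz) applied to the analysis channel
#'   before matching; 0.5-6 Hz removes drifts and alpha activity while
#'   keeping the P3 bump.
#' @param prefilter_order Butterworth order of the (two-way) pre-filter.
#' @param search_window Candidate latency window, seconds post-stimulus
#'   (default 0.35-0.9).
#' @param template_halfwidth Template half-width in seconds (cuts span
#'   +-0.5 s around the current latency estimate).
#' @param n_iterations Number of template-refinement iterations (default 4).
#' @param channel Analysis channel; the estimator is one-dimensional and
#'   the P3 is maximal at Pz.
#' @param score `"ncc"` (normalized cross-correlation, amplitude-invariant;
#'   default) or `"dot"` (raw sliding dot product).
#' @return A `woody_config` list.
#' @export
woody_config <- function(prefilter_band = c(0.5, 6), prefilter_order = 3,
                         search_window = c(0.35, 0.9),
                         template_halfwidth = 0.5, n_iterations = 4,
                         channel = "Pz", score = c("ncc", "dot")) {
  score <- match.arg(score)
  if (n_iterations < 1) stopf("woody_config: n_iterations must be >= 1")
  if (search_window[1] >= search_window[2])
    stopf("woody_config: search window must be increasing")
  structure(list(prefilter_band = prefilter_band,
                 prefilter_order = prefilter_order,
                 search_window = search_window,
                 template_halfwidth = template_halfwidth,
                 n_iterations = n_iterations, channel = channel,
                 score = score),
            class = "woody_config")
}

# extract the analysis channel as a trials x samples matrix, optionally
# band-pass filtered (two-way Butterworth, reflect padding)
woody_signal <- function(epochs, config, prefilter = TRUE) {
  ci <- match(config$channel, epochs$channel_names)
  if (is.na(ci))
    stopf("woody: channel '%s' not present in epochs", config$channel)
  X <- epochs$data[, ci, , drop = FALSE]
  X <- array(X, dim(X)[c(1, 3)])
  if (prefilter) {
    bf <- signal::butter(config$prefilter_order,
                         config$prefilter_band / (epochs$sfreq / 2),
                         type = "pass")
    pad <- ncol(X) - 1L
    for (i in seq_len(nrow(X))) X[i, ] <- filtfilt_padded(bf, X[i, ], pad)
  }
  X
}

# average +-H-sample cuts centred on per-trial estimates (sample indices);
# cuts truncated by the epoch edge contribute their overlapping part
build_template <- function(X, centers, H) {
  n <- ncol(X)
  acc <- numeric(2 * H + 1)
  cnt <- numeric(2 * H + 1)
  for (i in seq_len(nrow(X))) {
    c0 <- centers[i]
    o0 <- max(-H, 1 - c0); o1 <- min(H, n - c0)
    if (o1 < o0) next
    j <- (o0:o1) + H + 1
    acc[j] <- acc[j] + X[i, (c0 + o0):(c0 + o1)]
    cnt[j] <- cnt[j] + 1
  }
  tpl <- ifelse(cnt > 0, acc / pmax(cnt, 1), 0)
  tpl
}

# alignment reference of a template: its peak (earliest sample of the
# maximum); the centre sample for a degenerate all-equal template
template_ref <- function(template) {
  if (length(unique(template)) == 1) return((length(template) + 1L) %/% 2L)
  which.max(template)
}

# slide the template across the candidate positions; returns the trials x
# n_candidates score matrix. The candidate sample marks where the
# template's own peak (its argmax, `ref`) is placed, so the estimated
# latency is the latency of the P3 peak itself — a common offset between
# the initial estimates (RTs) and the true peaks is absorbed into the
# template and does not bias the estimates. ncc correlates over the
# overlapping support only (renormalized); dot sums raw products.
score_matrix <- function(X, template, cand, H, type = "ncc",
                         ref = template_ref(template)) {
  n <- ncol(X)
  L <- length(template)
  S <- matrix(NA_real_, nrow(X), length(cand))
  for (j in seq_along(cand)) {
    c0 <- cand[j]
    # template index ref sits at signal sample c0
    o0 <- max(1 - ref, 1 - c0); o1 <- min(L - ref, n - c0)
    if (o1 <= o0) next
    seg <- X[, (c0 + o0):(c0 + o1), drop = FALSE]
    tpl <- template[(o0:o1) + ref]
    if (type == "ncc") {
      tc <- tpl - mean(tpl)
      tn <- sqrt(sum(tc^2))
      if (tn == 0) next
      sc <- seg - rowMeans(seg)
      den <- sqrt(rowSums(sc^2)) * tn
      v <- as.numeric(sc %*% tc) / den
      v[den == 0] <- NA_real_
      S[, j] <- v
    } else {
      S[, j] <- as.numeric(seg %*% tpl)
    }
  }
  S
}

# largest positive local maximum of one score sequence (derivative
# sign-change definition; plateaus credited to their earliest sample;
# ties between equal maxima resolved to the earliest). NA when none.
pick_peak <- function(s) {
  n <- length(s)
  if (n < 3) return(NA_integer_)
  s[!is.finite(s)] <- -Inf
  is_max <- logical(n)
  for (j in 2:(n - 1)) is_max[j] <- s[j] > s[j - 1] && s[j] >= s[j + 1]
  pos <- which(is_max & s > 0)
  if (length(pos) == 0) return(NA_integer_)
  pos[which.max(s[pos])]
}

#' Cut matching-band epochs from a continuous recording
#'
#' Applies the 0.5-6 Hz two-way Butterworth pre-filter to the continuous
#' signal (filtering before cutting avoids the poor low-frequency
#' suppression of short-segment filtering) and epochs on the target
#' events. Use with `estimate_latencies(..., prefilter = FALSE)`.
#'
#' @param recording A [continuous_recording()] (post EOG regression, at
#'   the analysis rate).
#' @param metadata Behavioural trial table joined into the epochs.
#' @param config A [woody_config()] supplying the band and order.
#' @param lock_label,tmin,tmax Epoching parameters.
#' @return An `epoch_set` in the matching band.
#' @export
woody_epochs <- function(recording, metadata, config = woody_config(),
                         lock_label = "target", tmin = -0.1, tmax = 1.5) {
  rec <- bandpass_iir(recording, config$prefilter_band[1],
                      config$prefilter_band[2], config$prefilter_order)
  ep <- epoch_recording(rec, lock_label, tmin, tmax, metadata = metadata)
  reject_no_response(ep)
}

#' Estimate single-trial P3 latencies by iterative template matching
#'
#' Implements the modified Woody procedure on one channel: (1) take the
#' per-trial initial latency estimates (the RT, in the speeded condition);
#' (2) cut the signal ±0.5 s around the current estimates and average the
#' cuts into a "P3-locked" template; (3) per trial, slide the template
#' across every sample of the 350-900 ms search window and score the
#' match (normalized cross-correlation by default); (4) locate the local
#' maxima of the score sequence via derivative sign changes and take the
#' largest positive one as the new latency estimate; trials without a
#' positive local maximum keep their previous estimate and are flagged
#' (they still contribute to the next template). Steps (2)-(4) are
#' repeated `n_iterations` times.
#'
#' @param epochs A stimulus-locked `epoch_set` (t = 0 at target onset).
#' @param init_latencies Per-trial initial latency estimates in seconds
#'   from target onset (the trial RTs in the speeded condition).
#' @param config A [woody_config()].
#' @param prefilter Apply the 0.5-6 Hz two-way Butterworth pre-filter
#'   (default TRUE; set FALSE if the epochs are already in-band).
#' @return A `latency_table`: `data.frame` (`trial_id`, `latency_s`,
#'   `score`, `flagged`) with attributes `template` (numeric, with
#'   `sfreq`/`halfwidth`), `history` (per-iteration mean latency and mean
#'   absolute change), and the config echo.
#' @export
estimate_latencies <- function(epochs, init_latencies, config = woody_config(),
                               prefilter = TRUE) {
  n_tr <- dim(epochs$data)[1]
  if (length(init_latencies) != n_tr)
    stopf("estimate_latencies: need one initial latency per trial (%d != %d)",
          length(init_latencies), n_tr)
  X <- woody_signal(epochs, config, prefilter)
  fs <- epochs$sfreq
  H <- round(config$template_halfwidth * fs)
  tt <- epoch_times(epochs)
  cand <- which(tt >= config$search_window[1] & tt <= config$search_window[2])
  if (length(cand) < 3)
    stopf("estimate_latencies: search window is empty after clipping to the epoch")
  to_idx <- function(lat) pmin(pmax(round((lat - epochs$t0) * fs) + 1, 1),
                               ncol(X))
  est <- to_idx(init_latencies)
  flagged <- rep(FALSE, n_tr)
  score <- rep(NA_real_, n_tr)
  history <- data.frame(iteration = integer(0), mean_latency_s = numeric(0),
                        mean_abs_change_s = numeric(0))
  template <- NULL
  for (it in seq_len(config$n_iterations)) {
    template <- build_template(X, est, H)
    S <- score_matrix(X, template, cand, H, config$score)
    new_est <- est
    for (i in seq_len(n_tr)) {
      p <- pick_peak(S[i, ])
      if (is.na(p)) {
        flagged[i] <- TRUE
      } else {
        new_est[i] <- cand[p]
        score[i] <- S[i, p]
        flagged[i] <- FALSE
      }
    }
    if (all(flagged))
      warnf("estimate_latencies: iteration %d flagged every trial", it)
    change <- mean(abs(new_est - est)) / fs
    est <- new_est
    history <- rbind(history, data.frame(
      iteration = it, mean_latency_s = mean(tt[est]),
      mean_abs_change_s = change))
  }
  latency_table(epochs, est, score, flagged, template, history, config, fs)
}

latency_table <- function(epochs, est_idx, score, flagged, template, history,
                          config, fs) {
  tt <- epoch_times(epochs)
  out <- data.frame(trial_id = epochs$trials$trial_id,
                    latency_s = tt[est_idx], score = score, flagged = flagged,
                    stringsAsFactors = FALSE)
  attr(template, "sfreq") <- fs
  attr(template, "halfwidth_s") <- config$template_halfwidth
  attr(out, "template") <- template
  attr(out, "history") <- history
  attr(out, "config") <- config
  class(out) <- c("latency_table", "data.frame")
  out
}

#' Estimate latencies using a fixed initial template
#'
#' Runs one matching pass with the supplied template (e.g. the final
#' speeded-condition template, re-used for the delayed condition where
#' RTs fall outside the search window and cannot seed the iteration),
#' then the standard refinement loop for the remaining iterations. On the
#' first pass, trials without a positive local maximum fall back to the
#' global score argmax and are flagged.
#'
#' @param template Template from a previous [estimate_latencies()] run
#'   (the `"template"` attribute), sampled at the epochs' rate.
#' @param epochs A stimulus-locked `epoch_set`.
#' @param config A [woody_config()].
#' @param prefilter As in [estimate_latencies()].
#' @return A `latency_table`.
#' @export
reuse_template <- function(template, epochs, config = woody_config(),
                           prefilter = TRUE) {
  fs <- epochs$sfreq
  tfs <- attr(template, "sfreq")
  if (!is.null(tfs) && tfs != fs)
    stopf("reuse_template: template rate (%g Hz) != epoch rate (%g Hz)", tfs, fs)
  X <- woody_signal(epochs, config, prefilter)
  H <- (length(template) - 1L) %/% 2L
  tt <- epoch_times(epochs)
  cand <- which(tt >= config$search_window[1] & tt <= config$search_window[2])
  if (length(cand) < 3)
    stopf("reuse_template: search window is empty after clipping to the epoch")
  n_tr <- nrow(X)
  S <- score_matrix(X, template, cand, H, config$score)
  est <- integer(n_tr); flagged <- logical(n_tr); score <- rep(NA_real_, n_tr)
  for (i in seq_len(n_tr)) {
    p <- pick_peak(S[i, ])
    if (is.na(p)) {
      p <- which.max(replace(S[i, ], !is.finite(S[i, ]), -Inf))
      flagged[i] <- TRUE
    }
    est[i] <- cand[p]
    score[i] <- S[i, p]
  }
  history <- data.frame(iteration = 1L, mean_latency_s = mean(tt[est]),
                        mean_abs_change_s = NA_real_)
  tpl <- template
  if (config$n_iterations > 1) {
    for (it in seq(2, config$n_iterations)) {
      tpl <- build_template(X, est, H)
      S <- score_matrix(X, tpl, cand, H, config$score)
      new_est <- est
      for (i in seq_len(n_tr)) {
        p <- pick_peak(S[i, ])
        if (is.na(p)) {
          flagged[i] <- TRUE
        } else {
          new_est[i] <- cand[p]; score[i] <- S[i, p]; flagged[i] <- FALSE
        }
      }
      history <- rbind(history, data.frame(
        iteration = it, mean_latency_s = mean(tt[new_est]),
        mean_abs_change_s = mean(abs(new_est - est)) / fs))
      est <- new_est
    }
  }
  latency_table(epochs, est, score, flagged, tpl, history, config, fs)
}

#' Export a latency table as TSV
#' @param lat A `latency_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_latency_tsv <- function(lat, path) {
  utils::write.table(as.data.frame(lat), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
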