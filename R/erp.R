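#' Assign trials to equal-size bins by AS or RT
#'
#' Trials are stably sorted by the key (association strength descending or
#' RT ascending; ties broken by `trial_id`) and split into `n_bins`
#' contiguous blocks whose sizes differ by at most one; when the count is
#' not divisible, the extra trials go to the lowest-index bins. Bin 1 thus
#' holds the strongest associates (AS key) or the fastest responses (RT
#' key). Per-bin descriptives (mean/sd AS, mean/sd RT, response ratio)
#' are computed alongside.
#'
#' @param metadata Trial table with `trial_id`, `as_score`, `rt_s`,
#'   `response`.
#' @param key `"as"` (descending) or `"rt"` (ascending).
#' @param n_bins Number of bins (default 8).
#' @return A `bin_assignment`: list with `assignment` (`trial_id`, `bin`)
#'   and `summary` (one row per bin).
#' @export
bin_trials <- function(metadata, key = c("as", "rt"), n_bins = 8) {
  key <- match.arg(key)
  n <- nrow(metadata)
  if (n_bins > n)
    stopf("bin_trials: n_bins (%d) exceeds trial count (%d)", n_bins, n)
  kv <- switch(key, as = metadata$as_score, rt = metadata$rt_s)
  if (any(!is.finite(kv)))
    stopf("bin_trials: key '%s' has missing/non-finite values", key)
  ord <- order(if (key == "as") -kv else kv, metadata$trial_id)
  base <- n %/% n_bins
  extra <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, extra), rep(0L, n_bins - extra))
  bin <- rep(seq_len(n_bins), times = sizes)
  assignment <- data.frame(trial_id = metadata$trial_id[ord], bin = bin,
                           stringsAsFactors = FALSE)
  md <- metadata[ord, ]
  ratio <- function(r) {
    r <- r[!is.na(r)]
    if (length(r) == 0) NA_real_ else mean(r == "related")
  }
  summary <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    m <- md[bin == b, ]
    data.frame(bin = b, n = nrow(m),
               mean_as = mean(m$as_score), sd_as = stats::sd(m$as_score),
               mean_rt = mean(m$rt_s, na.rm = TRUE),
               sd_rt = stats::sd(m$rt_s, na.rm = TRUE),
               response_ratio = ratio(m$response))
  }))
  structure(list(assignment = assignment, summary = summary, key = key,
                 n_bins = n_bins, remainder = extra),
            class = "bin_assignment")
}

#' Per-bin average ERPs for one subject
#'
#' @param epochs An `epoch_set`.
#' @param assignment A [bin_trials()] result (trials not in the epoch set
#'   are ignored; every bin must retain at least one epoch).
#' @return An `erp_set`: `waveforms` (bins x channels x samples), `t0`,
#'   `sfreq`, `channel_names`, `lock`, `n_trials` per bin, `level`.
#' @export
average_erp <- function(epochs, assignment) {
  bins <- assignment$assignment
  idx <- match(epochs$trials$trial_id, bins$trial_id)
  bin_of <- bins$bin[idx]
  n_bins <- assignment$n_bins
  d <- dim(epochs$data)
  w <- array(NA_real_, c(n_bins, d[2], d[3]))
  n_trials <- integer(n_bins)
  for (b in seq_len(n_bins)) {
    sel <- which(!is.na(bin_of) & bin_of == b)
    if (length(sel) == 0) stopf("average_erp: bin %d has no epochs", b)
    n_trials[b] <- length(sel)
    w[b, , ] <- apply(epochs$data[sel, , , drop = FALSE], c(2, 3), mean)
  }
  structure(list(waveforms = w, t0 = epochs$t0, sfreq = epochs$sfreq,
                 channel_names = epochs$channel_names, lock = epochs$lock,
                 n_trials = n_trials, level = "subject"),
            class = "erp_set")
}

#' Grand-average ERPs across subjects
#'
#' Unweighted mean of the per-subject bin ERPs (each subject contributes
#' equally regardless of trial counts).
#'
#' @param erp_list List of subject-level `erp_set`s with identical shape.
#' @return A grand-level `erp_set`.
#' @export
grand_average <- function(erp_list) {
  stopifnot(length(erp_list) >= 1)
  d1 <- dim(erp_list[[1]]$waveforms)
  for (e in erp_list)
    if (!identical(dim(e$waveforms), d1))
      stopf("grand_average: subjects have differing ERP dimensions")
  w <- Reduce(`+`, lapply(erp_list, `[[`, "waveforms")) / length(erp_list)
  out <- erp_list[[1]]
  out$waveforms <- w
  out$n_trials <- Reduce(`+`, lapply(erp_list, `[[`, "n_trials"))
  out$level <- "grand"
  out
}

#' Re-cut stimulus-locked epochs around the response onset
#'
#' For each trial with a known response onset (metadata `rt_s`, seconds
#' from the stimulus-lock event), cuts the window `response + window` out
#' of the source epoch. Trials whose window exceeds the source epoch, or
#' without a response, are dropped and logged.
#'
#' @param epochs A stimulus-locked `epoch_set`.
#' @param window Window around the response in seconds (default ±0.5 s).
#' @return A response-locked `epoch_set`.
#' @export
relock_to_response <- function(epochs, window = c(-0.5, 0.5)) {
  fs <- epochs$sfreq
  n_src <- dim(epochs$data)[3]
  m <- round((window[2] - window[1]) * fs)
  rt <- epochs$trials$rt_s
  # index of the source sample at time rt + window[1]
  i0 <- round((rt + window[1] - epochs$t0) * fs) + 1
  ok <- !is.na(rt) & i0 >= 1 & (i0 + m - 1) <= n_src
  drop_log <- data.frame(
    trial_id = epochs$trials$trial_id[!ok],
    reason = ifelse(is.na(rt[!ok]), "no response onset",
                    "response window outside source epoch"),
    stringsAsFactors = FALSE)
  dat <- array(0, c(sum(ok), dim(epochs$data)[2], m))
  kk <- which(ok)
  for (j in seq_along(kk))
    dat[j, , ] <- epochs$data[kk[j], , i0[kk[j]]:(i0[kk[j]] + m - 1)]
  epoch_set(dat, t0 = window[1], sfreq = fs,
            channel_names = epochs$channel_names, lock = "response",
            trials = epochs$trials[ok, , drop = FALSE],
            log = log_step(epochs$log, "relock_to_response",
                           list(window = window, n_kept = sum(ok),
                                n_dropped = sum(!ok))),
            drop_log = rbind(epochs$drop_log, drop_log))
}

#' Mean amplitude in a channel/time window
#'
#' Arithmetic mean over the in-window samples (half-open `[w1, w2)`)
#' at one channel: per trial for an `epoch_set`, per bin for an `erp_set`.
#' The canonical N400 quantification is Pz over 300-500 ms; the
#' group-contrast window is Pz over 400-500 ms.
#'
#' @param x An `epoch_set` or `erp_set`.
#' @param channel Channel name (default "Pz").
#' @param window Time window in seconds relative to the lock event.
#' @return Numeric vector of window means (microvolt).
#' @export
mean_amplitude <- function(x, channel = "Pz", window = c(0.3, 0.5)) {
  ci <- match(channel, x$channel_names)
  if (is.na(ci)) stopf("mean_amplitude: channel '%s' not present", channel)
  dat <- if (inherits(x, "erp_set")) x$waveforms else x$data
  tt <- x$t0 + (seq_len(dim(dat)[3]) - 1) / x$sfreq
  sel <- which(tt >= window[1] & tt < window[2])
  if (length(sel) == 0)
    stopf("mean_amplitude: window [%g, %g) outside epoch span [%g, %g]",
          window[1], window[2], tt[1], tt[length(tt)])
  apply(dat[, ci, sel, drop = FALSE], 1, mean)
}

#' Scalp topography snapshot
#'
#' Channel vector at the sample nearest to `time_s`, for one bin of an
#' `erp_set`, optionally as the difference between two bins.
#'
#' @param erp An `erp_set`.
#' @param time_s Time in seconds relative to the lock event.
#' @param bin Bin index (default 1).
#' @param minus_bin Optional second bin subtracted from `bin`.
#' @return Named numeric vector, one value per channel.
#' @export
topography <- function(erp, time_s, bin = 1, minus_bin = NULL) {
  tt <- erp$t0 + (seq_len(dim(erp$waveforms)[3]) - 1) / erp$sfreq
  if (time_s < tt[1] || time_s > tt[length(tt)])
    stopf("topography: time %g s outside epoch span [%g, %g]",
          time_s, tt[1], tt[length(tt)])
  k <- which.min(abs(tt - time_s))
  v <- erp$waveforms[bin, , k]
  if (!is.null(minus_bin)) v <- v - erp$waveforms[minus_bin, , k]
  names(v) <- erp$channel_names
  v
}

#' Export per-bin descriptives as TSV
#' @param assignment A `bin_assignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bin_summary_tsv <- function(assignment, path) {
  utils::write.table(assignment$summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
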