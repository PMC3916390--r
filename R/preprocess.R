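#' Zero-phase (two-way) Butterworth band-pass filter
#'
#' Designs an order-`order` Butterworth band-pass and applies it forward
#' and backward ("two-way"), so the net phase shift is zero and the
#' effective magnitude response is the squared one-pass response. The
#' signal is extended by odd (point-mirrored) reflection before filtering
#' to suppress edge transients; the default padding is at least three
#' times the filter's impulse-response settling length (the point beyond
#' which the impulse response stays under 1% of its peak).
#'
#' @param recording A [continuous_recording()].
#' @param low_hz,high_hz Band edges, 0 < low < high < Nyquist.
#' @param order Filter order of the one-pass design (default 3).
#' @param pad Padding length in samples; `NULL` derives it from the
#'   settling length.
#' @return A filtered copy of `recording`.
#' @export
bandpass_iir <- function(recording, low_hz, high_hz, order = 3, pad = NULL) {
  fs <- recording$sfreq
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2))
    stopf("bandpass_iir: need 0 < low (%g) < high (%g) < Nyquist (%g)",
          low_hz, high_hz, fs / 2)
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  n <- ncol(recording$data)
  if (is.null(pad)) pad <- 3L * settling_length(bf, fs)
  pad <- min(as.integer(pad), n - 1L)
  out <- recording
  for (i in seq_len(nrow(out$data)))
    out$data[i, ] <- filtfilt_padded(bf, out$data[i, ], pad)
  out$log <- log_step(out$log, "bandpass_iir",
                      list(low_hz = low_hz, high_hz = high_hz, order = order,
                           pad = pad))
  out
}

# samples until the impulse response stays below 1% of its peak magnitude
settling_length <- function(bf, fs, frac = 0.01, cap_s = 30) {
  n <- as.integer(min(cap_s * fs, 2^20))
  h <- signal::filter(bf, c(1, numeric(n - 1)))
  thr <- frac * max(abs(h))
  idx <- which(abs(h) > thr)
  if (length(idx) == 0) 1L else max(idx)
}

# forward-backward filtering with odd-reflection padding
filtfilt_padded <- function(bf, x, pad) {
  n <- length(x)
  pad <- max(0L, min(pad, n - 1L))
  if (pad > 0) {
    left <- 2 * x[1] - x[seq(pad + 1, 2)]
    right <- 2 * x[n] - x[seq(n - 1, n - pad)]
    xp <- c(left, x, right)
  } else xp <- x
  y <- signal::filter(bf, xp)
  y <- rev(signal::filter(bf, rev(y)))
  y[(pad + 1):(pad + n)]
}

#' Resample a recording (default chain: 512 -> 256 Hz)
#'
#' Integer-factor downsampling is performed by decimation without an
#' additional anti-alias filter: in the standard chain the preceding
#' 0.1-50 Hz band-pass already limits the bandwidth below the target
#' Nyquist. Non-integer ratios use polyphase resampling
#' ([signal::resample()]). Event sample indices are remapped by the rate
#' ratio with round-half-away-from-zero; total duration is preserved
#' within one output sample.
#'
#' @param recording A [continuous_recording()].
#' @param target_hz Target rate (default 256).
#' @return A resampled copy.
#' @export
resample_recording <- function(recording, target_hz = 256) {
  fs <- recording$sfreq
  if (target_hz == fs) return(recording)
  if (target_hz > fs)
    warnf("resample_recording: upsampling %g -> %g Hz requested", fs, target_hz)
  r <- target_hz / fs
  out <- recording
  if (target_hz < fs && fs %% target_hz == 0) {
    q <- fs %/% target_hz
    out$data <- recording$data[, seq(1, ncol(recording$data), by = q),
                               drop = FALSE]
  } else {
    gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)
    scale <- 1e6
    p <- round(target_hz * scale); q <- round(fs * scale)
    g <- gcd(p, q); p <- p / g; q <- q / g
    out$data <- t(apply(recording$data, 1,
                        function(x) signal::resample(x, p, q)))
  }
  out$sfreq <- target_hz
  if (nrow(out$events) > 0) {
    # 1-based index <-> 0-based time grid
    out$events$sample <- as.integer(
      round_half_away((recording$events$sample - 1) * r) + 1)
    out$events$sample <- pmin(pmax(out$events$sample, 1L), ncol(out$data))
  }
  out$log <- log_step(out$log, "resample",
                      list(from_hz = fs, to_hz = target_hz))
  out
}

#' Attenuate ocular artifacts by EOG regression
#'
#' Per EEG channel, ordinary least-squares leakage coefficients onto the
#' (demeaned) EOG regressor(s) are estimated over the whole recording and
#' the fitted EOG contribution is subtracted. EOG channels are retained
#' unmodified. Channels whose EOG regressor has zero variance are skipped
#' with a warning.
#'
#' @param recording A [continuous_recording()].
#' @param eog_channel_names Names of the EOG channel(s) (default "EOG").
#' @return A corrected copy; estimated coefficients are stored in the
#'   processing log (`coefficients`, channels x EOG regressors).
#' @export
regress_eog <- function(recording, eog_channel_names = "EOG") {
  miss <- setdiff(eog_channel_names, recording$channel_names)
  if (length(miss))
    stopf("regress_eog: EOG channel(s) not found: %s", paste(miss, collapse = ", "))
  E <- t(recording$data[eog_channel_names, , drop = FALSE])
  v <- apply(E, 2, stats::var)
  if (any(v == 0)) {
    warnf("regress_eog: zero-variance EOG regressor(s) %s skipped",
          paste(eog_channel_names[v == 0], collapse = ", "))
    E <- E[, v > 0, drop = FALSE]
    if (ncol(E) == 0) return(recording)
  }
  Ec <- scale(E, center = TRUE, scale = FALSE)
  eeg_rows <- which(!recording$channel_names %in% eog_channel_names)
  out <- recording
  XtXinv <- solve(crossprod(Ec))
  B <- matrix(0, length(eeg_rows), ncol(Ec),
              dimnames = list(recording$channel_names[eeg_rows], colnames(E)))
  for (j in seq_along(eeg_rows)) {
    y <- recording$data[eeg_rows[j], ]
    b <- XtXinv %*% crossprod(Ec, y)
    out$data[eeg_rows[j], ] <- y - as.numeric(Ec %*% b)
    B[j, ] <- b
  }
  out$log <- log_step(out$log, "regress_eog",
                      list(eog_channels = eog_channel_names,
                           coefficients = B))
  out
}

#' Construct an epoch set
#'
#' @param data Trials x channels x samples array.
#' @param t0 Time of the first sample relative to the lock event (s).
#' @param sfreq Sampling rate.
#' @param channel_names Channel labels.
#' @param lock `"stimulus"`, `"response"` or `"cue"`.
#' @param trials Per-trial metadata `data.frame` (must carry `trial_id`).
#' @param log Provenance list.
#' @param drop_log `data.frame` of dropped trials (`trial_id`, `reason`).
#' @return An `epoch_set`.
#' @export
epoch_set <- function(data, t0, sfreq, channel_names, lock, trials,
                      log = list(), drop_log = NULL) {
  stopifnot(length(dim(data)) == 3, dim(data)[1] == nrow(trials),
            dim(data)[2] == length(channel_names))
  if (t0 > 0) stopf("epoch_set: t0 must not be positive (lock event inside epoch)")
  if (is.null(drop_log))
    drop_log <- data.frame(trial_id = character(0), reason = character(0),
                           stringsAsFactors = FALSE)
  structure(list(data = data, t0 = t0, sfreq = sfreq,
                 channel_names = channel_names, lock = lock, trials = trials,
                 log = log, drop_log = drop_log),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz, %s-locked, t0 = %g s\n",
              d[1], d[2], d[3], x$sfreq, x$lock, x$t0))
  invisible(x)
}

#' Sample times of an epoch set
#' @param epochs An `epoch_set`.
#' @return Numeric vector, seconds relative to the lock event.
#' @export
epoch_times <- function(epochs) {
  epochs$t0 + (seq_len(dim(epochs$data)[3]) - 1) / epochs$sfreq
}

#' Cut a continuous recording into event-locked epochs
#'
#' One epoch per event carrying `lock_label`, spanning the half-open
#' window `[tmin, tmax)` in sample space with t = 0 at the event sample.
#' Trial metadata is joined by `trial_id`. Epochs exceeding the recording
#' bounds are dropped and logged.
#'
#' @param recording A [continuous_recording()].
#' @param lock_label Event label to lock to (e.g. "target", "response").
#' @param tmin,tmax Epoch window in seconds (default -0.1 .. 1.5).
#' @param metadata Optional `data.frame` with `trial_id` to join.
#' @param lock Lock type stored on the result; defaults from the label.
#' @return An [epoch_set()].
#' @export
epoch_recording <- function(recording, lock_label, tmin = -0.1, tmax = 1.5,
                            metadata = NULL, lock = NULL) {
  ev <- recording$events[recording$events$label == lock_label, , drop = FALSE]
  if (nrow(ev) == 0)
    stopf("epoch_recording: no events labelled '%s'", lock_label)
  fs <- recording$sfreq
  n_samp <- round((tmax - tmin) * fs)
  off0 <- round(tmin * fs)
  n_rec <- ncol(recording$data)
  starts <- ev$sample + off0
  ok <- starts >= 1 & (starts + n_samp - 1) <= n_rec
  drop_log <- data.frame(trial_id = ev$trial_id[!ok],
                         reason = rep("epoch outside recording bounds", sum(!ok)),
                         stringsAsFactors = FALSE)
  ev <- ev[ok, , drop = FALSE]; starts <- starts[ok]
  dat <- array(0, c(nrow(ev), nrow(recording$data), n_samp))
  for (k in seq_len(nrow(ev)))
    dat[k, , ] <- recording$data[, starts[k]:(starts[k] + n_samp - 1)]
  trials <- data.frame(trial_id = ev$trial_id, stringsAsFactors = FALSE)
  if (!is.null(metadata))
    trials <- merge(trials, metadata, by = "trial_id", all.x = TRUE,
                    sort = FALSE)
  trials <- trials[match(ev$trial_id, trials$trial_id), , drop = FALSE]
  rownames(trials) <- NULL
  if (is.null(lock))
    lock <- switch(lock_label, target = "stimulus", prime = "stimulus",
                   response = "response", cue = "cue", "stimulus")
  epoch_set(dat, t0 = off0 / fs, sfreq = fs,
            channel_names = recording$channel_names, lock = lock,
            trials = trials,
            log = log_step(recording$log, "epoch",
                           list(lock_label = lock_label, tmin = tmin,
                                tmax = tmax, n_kept = nrow(ev),
                                n_dropped = nrow(drop_log))),
            drop_log = drop_log)
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over the baseline window
#' (half-open `[window[1], window[2])` in sample space).
#'
#' @param epochs An `epoch_set`.
#' @param window Baseline window in seconds (default the 0.1 s before the
#'   lock event).
#' @return A corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, window = c(-0.1, 0)) {
  tt <- epoch_times(epochs)
  sel <- which(tt >= window[1] & tt < window[2])
  if (length(sel) == 0)
    stopf("baseline_correct: empty baseline window [%g, %g)", window[1], window[2])
  bl <- apply(epochs$data[, , sel, drop = FALSE], c(1, 2), mean)
  out <- epochs
  out$data <- epochs$data - as.vector(bl)  # recycles over the sample dim
  out$log <- log_step(out$log, "baseline_correct", list(window = window))
  out
}

#' Discard trials without a (timely) button response
#'
#' Retains only trials whose metadata `missed` flag is `FALSE`; counts are
#' recorded in the processing log.
#'
#' @param epochs An `epoch_set` whose `trials` carry a logical `missed`.
#' @return The filtered `epoch_set`.
#' @export
reject_no_response <- function(epochs) {
  if (is.null(epochs$trials$missed))
    stopf("reject_no_response: trial metadata lacks a 'missed' flag")
  keep <- !epochs$trials$missed
  out <- subset_epochs(epochs, keep)
  if (sum(keep) == 0) warnf("reject_no_response: all trials were missed")
  out$log <- log_step(out$log, "reject_no_response",
                      list(n_in = length(keep), n_kept = sum(keep),
                           n_rejected = sum(!keep)))
  out
}

#' Subset an epoch set by trial
#' @param epochs An `epoch_set`.
#' @param idx Logical or integer trial index.
#' @return The subset `epoch_set`.
#' @export
subset_epochs <- function(epochs, idx) {
  out <- epochs
  out$data <- epochs$data[idx, , , drop = FALSE]
  out$trials <- epochs$trials[idx, , drop = FALSE]
  rownames(out$trials) <- NULL
  out
}

#' Run the standard preprocessing chain on a continuous recording
#'
#' Fixed stage order: wide band-pass (0.1-50 Hz) -> resample to 256 Hz ->
#' EOG regression -> narrow band-pass (0.5-15 Hz) -> stimulus-locked
#' epoching (-0.1..1.5 s) -> baseline correction (-0.1..0 s) -> rejection
#' of no-response trials. Every stage logs its parameters.
#'
#' @param recording A [continuous_recording()].
#' @param metadata Behavioural trial table joined into the epochs.
#' @param wide_band,narrow_band Band edges in Hz.
#' @param target_hz Resampling target.
#' @param lock_label Event to epoch on (default "target").
#' @param tmin,tmax,baseline_window Epoching/baseline windows (s).
#' @param eog_channel_names EOG channel names ("EOG").
#' @return A baseline-corrected, rejected `epoch_set`.
#' @export
preprocess_chain <- function(recording, metadata,
                             wide_band = c(0.1, 50), narrow_band = c(0.5, 15),
                             target_hz = 256, lock_label = "target",
                             tmin = -0.1, tmax = 1.5,
                             baseline_window = c(-0.1, 0),
                             eog_channel_names = "EOG") {
  rec <- bandpass_iir(recording, wide_band[1], wide_band[2])
  rec <- resample_recording(rec, target_hz)
  rec <- regress_eog(rec, eog_channel_names)
  rec <- bandpass_iir(rec, narrow_band[1], narrow_band[2])
  ep <- epoch_recording(rec, lock_label, tmin, tmax, metadata = metadata)
  ep <- baseline_correct(ep, baseline_window)
  reject_no_response(ep)
}
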