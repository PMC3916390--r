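#' Configuration for the synthetic EEG generator
#'
#' @param condition `"speeded"` or `"delayed"`.
#' @param sfreq_raw Raw simulation rate in Hz; must be >= 512 so the
#'   wide-band filter + 256 Hz resampling stage is exercised.
#' @param channel_names Montage including an `"EOG"` channel; must contain
#'   `Pz`.
#' @param component_specs List of [component_spec()]s; `NULL` takes
#'   [default_component_specs()] for the condition.
#' @param noise List: `pink_rms` 1/f background RMS within 0.5-50 Hz
#'   (microvolt; 0 disables), `pink_exponent` spectral exponent,
#'   `alpha_rms` RMS of the amplitude-modulated alpha rhythm (the
#'   dominant ongoing rhythm at posterior sites), `alpha_freq` Hz.
#' @param eog List: `blink_rate` blinks per second (Poisson), `blink_amp`
#'   microvolt, `blink_width` Gaussian SD seconds, `noise_rms` EOG-channel
#'   measurement noise, `propagation` named per-channel leakage gains
#'   (`NULL` takes [default_eog_propagation()]).
#' @param trial_pitch_s Trial-onset spacing; `NULL` picks 2.5 s (speeded:
#'   0.2 s prime, 0.5 s SOA, 1 s target, 1 s blank) or 3.0 s (delayed:
#'   target on screen 1.5 s).
#' @param soa_s Prime-to-target stimulus onset asynchrony (0.5 s).
#' @param cue_s Cue time, seconds after target onset (delayed: 1.0 s).
#' @param pad_s Silent padding at both ends of the recording.
#' @param p3_jitter_sd,p3_amplitude_uv Convenience passthroughs applied
#'   when `component_specs` is `NULL`.
#' @param zero_as_latent Latent log-AS floor for AS = 0 (amplitude rules).
#' @param seed Default seed used by [simulate_eeg()] when none is given.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(condition = c("speeded", "delayed"),
                              sfreq_raw = 512,
                              channel_names = default_montage(32),
                              component_specs = NULL,
                              noise = list(pink_rms = 4.5, pink_exponent = 1,
                                           alpha_rms = 8, alpha_freq = 10),
                              eog = list(blink_rate = 0.1, blink_amp = 120,
                                         blink_width = 0.12, noise_rms = 3,
                                         propagation = NULL),
                              trial_pitch_s = NULL, soa_s = 0.5, cue_s = 1.0,
                              pad_s = 2.0,
                              p3_jitter_sd = 0.05, p3_amplitude_uv = 8,
                              zero_as_latent = -2, seed = NULL) {
  condition <- match.arg(condition)
  if (sfreq_raw < 512)
    stopf("simulation_config: sfreq_raw must be >= 512 Hz, got %g", sfreq_raw)
  if (!"Pz" %in% channel_names)
    stopf("simulation_config: montage must contain Pz")
  if (!"EOG" %in% channel_names)
    stopf("simulation_config: montage must contain an EOG channel")
  if (is.null(component_specs))
    component_specs <- default_component_specs(
      channel_names, condition,
      p3_amplitude_uv = p3_amplitude_uv, p3_jitter_sd = p3_jitter_sd)
  if (is.null(eog$propagation))
    eog$propagation <- default_eog_propagation(channel_names)
  if (is.null(trial_pitch_s))
    trial_pitch_s <- if (condition == "speeded") 2.5 else 3.0
  structure(list(condition = condition, sfreq_raw = sfreq_raw,
                 channel_names = channel_names,
                 component_specs = component_specs, noise = noise, eog = eog,
                 trial_pitch_s = trial_pitch_s, soa_s = soa_s, cue_s = cue_s,
                 pad_s = pad_s, zero_as_latent = zero_as_latent, seed = seed),
            class = "simulation_config")
}

# 1/f^exponent noise via spectral shaping. `rms` is the target RMS within
# `band` (Hz) when `fs` and `band` are given — a record-length-independent
# normalization (pure 1/f broadband RMS grows with duration) — otherwise
# the broadband RMS.
pink_noise <- function(n, exponent = 1, rms = 1, fs = NULL, band = NULL) {
  if (rms <= 0) return(numeric(n))
  nf <- n %/% 2
  f <- seq_len(nf)
  mag <- f^(-exponent / 2)
  ph <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = mag, argument = ph)
  full <- complex(length.out = n)
  full[2:(nf + 1)] <- spec
  full[n:(n - nf + 2)] <- Conj(spec[1:(nf - 1)])
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  if (!is.null(fs) && !is.null(band)) {
    hz <- f * fs / n
    inb <- hz >= band[1] & hz <= band[2]
    # fraction of total spectral power lying in the band
    frac <- sum(mag[inb]^2) / sum(mag^2)
    x * rms / (stats::sd(x) * sqrt(frac))
  } else {
    x * rms / stats::sd(x)
  }
}

#' Simulate a continuous EEG recording for one subject
#'
#' Composes, at the raw rate, background 1/f ("pink") noise plus an
#' amplitude-modulated alpha rhythm on every EEG channel, an EOG channel
#' carrying Poisson-timed blink transients, leakage of the EOG into every
#' EEG channel with known per-channel gains, and the condition's ERP
#' components placed trial by trial according to their latency rules.
#' Event markers are written for prime onset, target onset, the response
#' cue (delayed condition) and response onset. Ground truth (true P3
#' latency, true N400 Pz amplitude, response onset) is returned for every
#' trial.
#'
#' @param trials Behavioural table for a single subject and condition
#'   (see [simulate_behavior()]).
#' @param config A [simulation_config()].
#' @param seed Integer seed; falls back to `config$seed`.
#' @return A list with elements `recording` (a [continuous_recording()])
#'   and `ground_truth` (a `data.frame`: `trial_id`, `p3_latency_s`,
#'   `n400_amp_uv`, `response_onset_s`, all in seconds from target onset
#'   where applicable).
#' @export
simulate_eeg <- function(trials, config, seed = NULL) {
  if (length(unique(trials$subject_id)) != 1)
    stopf("simulate_eeg: trials must belong to a single subject")
  if (length(unique(trials$condition)) != 1 ||
      unique(trials$condition) != config$condition)
    stopf("simulate_eeg: trial condition does not match config$condition")
  bad <- which(!trials$missed & trials$rt_s <= 0)
  if (length(bad))
    stopf("simulate_eeg: response before target onset in trial(s) %s",
          paste(trials$trial_id[bad], collapse = ", "))
  seed <- seed %||% config$seed
  if (!is.null(seed)) set.seed(seed)

  fs <- config$sfreq_raw
  ch <- config$channel_names
  n_ch <- length(ch)
  n_tr <- nrow(trials)
  dur <- 2 * config$pad_s + n_tr * config$trial_pitch_s
  n <- ceiling(dur * fs)
  t_idx <- function(t) round_half_away(t * fs) + 1L  # time 0 -> sample 1

  data <- matrix(0, n_ch, n, dimnames = list(ch, NULL))
  eeg_rows <- which(ch != "EOG")

  # --- background noise ---------------------------------------------------
  if (config$noise$pink_rms > 0) {
    # pink_rms is the RMS within 0.5-50 Hz (record-length independent)
    for (i in eeg_rows)
      data[i, ] <- pink_noise(n, config$noise$pink_exponent,
                              config$noise$pink_rms, fs = fs,
                              band = c(0.5, 50))
  }
  if ((config$noise$alpha_rms %||% 0) > 0) {
    tt <- (seq_len(n) - 1) / fs
    for (i in eeg_rows) {
      env <- 1 + 0.6 * sin(2 * pi * 0.08 * tt + stats::runif(1, 0, 2 * pi))
      a <- sin(2 * pi * config$noise$alpha_freq * tt +
                 stats::runif(1, 0, 2 * pi)) * env
      data[i, ] <- data[i, ] + a * config$noise$alpha_rms / stats::sd(a)
    }
  }

  # --- ocular channel + propagation --------------------------------------
  eog <- numeric(n)
  if ((config$eog$blink_amp %||% 0) > 0 && (config$eog$blink_rate %||% 0) > 0) {
    n_blinks <- stats::rpois(1, config$eog$blink_rate * dur)
    if (n_blinks > 0) {
      centers <- stats::runif(n_blinks, 0, dur)
      w <- config$eog$blink_width
      for (c0 in centers) {
        i0 <- max(1L, t_idx(c0 - 5 * w)); i1 <- min(n, t_idx(c0 + 5 * w))
        tt <- (seq(i0, i1) - 1) / fs
        eog[i0:i1] <- eog[i0:i1] +
          config$eog$blink_amp * exp(-(tt - c0)^2 / (2 * w^2))
      }
    }
  }
  if ((config$eog$noise_rms %||% 0) > 0)
    eog <- eog + stats::rnorm(n, 0, config$eog$noise_rms)
  data["EOG", ] <- eog
  gains <- config$eog$propagation[ch]
  for (i in eeg_rows) if (gains[i] != 0) data[i, ] <- data[i, ] + gains[i] * eog

  # --- event timeline -----------------------------------------------------
  prime_t <- config$pad_s + (seq_len(n_tr) - 1) * config$trial_pitch_s
  target_t <- prime_t + config$soa_s
  events <- data.frame(
    sample = c(t_idx(prime_t), t_idx(target_t)),
    label = rep(c("prime", "target"), each = n_tr),
    trial_id = rep(trials$trial_id, 2), stringsAsFactors = FALSE)
  if (config$condition == "delayed") {
    events <- rbind(events, data.frame(
      sample = t_idx(target_t + config$cue_s), label = "cue",
      trial_id = trials$trial_id, stringsAsFactors = FALSE))
  }
  resp_ok <- !trials$missed & !is.na(trials$rt_s)
  if (any(resp_ok)) {
    events <- rbind(events, data.frame(
      sample = t_idx(target_t[resp_ok] + trials$rt_s[resp_ok]),
      label = "response", trial_id = trials$trial_id[resp_ok],
      stringsAsFactors = FALSE))
  }
  events <- events[order(events$sample), ]

  # --- components ---------------------------------------------------------
  gt <- data.frame(trial_id = trials$trial_id,
                   p3_latency_s = NA_real_,
                   n400_amp_uv = NA_real_,
                   response_onset_s = ifelse(resp_ok, trials$rt_s, NA_real_),
                   stringsAsFactors = FALSE)
  for (spec in config$component_specs) {
    amp <- component_amplitude(spec, trials$as_score, config$zero_as_latent)
    lat <- spec$latency
    center_rel <- switch(lat$type,  # seconds from target onset
      stimulus = rep(lat$offset, n_tr),
      rt = trials$rt_s + lat$offset,
      cue = rep(config$cue_s + lat$offset, n_tr),
      response = trials$rt_s + lat$offset,
      column = trials[[lat$column]] + lat$offset,
      stopf("unknown latency rule '%s'", lat$type))
    if (lat$jitter_sd > 0)
      center_rel <- center_rel + stats::rnorm(n_tr, 0, lat$jitter_sd)
    # response-anchored components are skipped on missed trials
    skip <- is.na(center_rel) |
      (lat$type %in% c("rt", "response") & !resp_ok)
    if (spec$name == "P3")
      gt$p3_latency_s <- ifelse(skip, NA_real_, center_rel)
    if (spec$name == "N400")
      gt$n400_amp_uv <- amp * spec$topography[["Pz"]]
    sup <- component_support(spec$waveform$shape, spec$waveform$width_s)
    topo <- spec$topography[ch]
    for (k in which(!skip)) {
      c_abs <- target_t[k] + center_rel[k]
      i0 <- max(1L, t_idx(c_abs - sup)); i1 <- min(n, t_idx(c_abs + sup))
      if (i1 < i0) next
      tt <- (seq(i0, i1) - 1) / fs
      wf <- component_waveform(spec$waveform$shape, spec$waveform$width_s,
                               tt, c_abs)
      data[, i0:i1] <- data[, i0:i1] + outer(topo * amp[k], wf)
    }
  }

  rec <- continuous_recording(
    data, fs, ch, events,
    log = log_step(list(), "simulate_eeg",
                   list(condition = config$condition, n_trials = n_tr,
                        sfreq_raw = fs, seed = seed)))
  list(recording = rec, ground_truth = gt)
}
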