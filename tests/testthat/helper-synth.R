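# shared fixture builders (all fixtures are generated in code)

# single-channel (Pz) epoch set containing one Gaussian bump per trial at
# known latency, plus optional per-trial additive noise from noise_fun(n)
make_bump_epochs <- function(lat, amp = 1, width = 0.09, fs = 256,
                             tmin = -0.1, tmax = 1.5, rt = lat,
                             noise_fun = NULL) {
  ntr <- length(lat)
  n <- round((tmax - tmin) * fs)
  tt <- tmin + (0:(n - 1)) / fs
  X <- array(0, c(ntr, 1, n))
  for (i in seq_len(ntr)) {
    X[i, 1, ] <- amp * exp(-(tt - lat[i])^2 / (2 * width^2))
    if (!is.null(noise_fun)) X[i, 1, ] <- X[i, 1, ] + noise_fun(n)
  }
  epoch_set(X, t0 = tmin, sfreq = fs, channel_names = "Pz",
            lock = "stimulus",
            trials = data.frame(trial_id = sprintf("t%04d", seq_len(ntr)),
                                rt_s = rt, missed = FALSE,
                                stringsAsFactors = FALSE))
}

# independent analytic oracle for the injected component sum of one trial:
# evaluates every component's waveform directly on the epoch time grid
# (seconds relative to target onset), bypassing the generator's sample
# placement code
component_sum_oracle <- function(trial, config, times, p3_center = NULL,
                                 channel = "Pz") {
  out <- numeric(length(times))
  for (spec in config$component_specs) {
    gain <- spec$topography[[channel]]
    amp <- switch(spec$amplitude$type,
      constant = spec$amplitude$base,
      linear_logas = spec$amplitude$base + spec$amplitude$slope *
        (if (trial$as_score >= 1) log(trial$as_score) else config$zero_as_latent))
    center <- switch(spec$latency$type,
      stimulus = spec$latency$offset,
      rt = trial$rt_s + spec$latency$offset,
      response = trial$rt_s + spec$latency$offset,
      cue = config$cue_s + spec$latency$offset,
      column = trial[[spec$latency$column]] + spec$latency$offset)
    if (spec$name == "P3" && !is.null(p3_center)) center <- p3_center
    if (is.na(center)) next
    d <- times - center
    w <- spec$waveform$width_s
    wf <- switch(spec$waveform$shape,
      gauss = exp(-d^2 / (2 * w^2)),
      halfsine = ifelse(abs(d) <= w, cos(pi * d / (2 * w)), 0),
      ramp = ifelse(d >= -w & d <= 0, (d + w) / w, 0))
    out <- out + gain * amp * wf
  }
  out
}

# independent exhaustive peak-pick oracle: all interior local maxima by
# pairwise comparison, positive values only, argmax (earliest on ties)
oracle_pick_peak <- function(s) {
  s[!is.finite(s)] <- -Inf
  n <- length(s)
  best <- NA_integer_; best_v <- -Inf
  for (j in 2:(n - 1)) {
    if (s[j] > s[j - 1] && s[j] >= s[j + 1] && s[j] > 0 && s[j] > best_v) {
      best <- j; best_v <- s[j]
    }
  }
  best
}

# quiet wrapper for simulations that legitimately warn
quiet <- function(expr) suppressWarnings(suppressMessages(expr))
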