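#' Window mean of the unit N400 waveform after the analysis chain
#'
#' The preprocessing chain is linear, so the injected contribution of the
#' N400 to a windowed Pz mean equals its ground-truth peak amplitude times
#' the window mean of the unit waveform passed through the same filters
#' (narrow band-pass, baseline correction). This factor converts
#' ground-truth amplitudes into expected measured window means.
#'
#' @param window Analysis window in seconds (default 0.4-0.5).
#' @param latency,width N400 peak latency and Gaussian SD (s).
#' @param fs Analysis sampling rate (Hz).
#' @param narrow_band Analysis band-pass applied by the chain (Hz).
#' @param baseline_window Baseline window (s).
#' @return Scalar factor.
#' @export
n400_window_factor <- function(window = c(0.4, 0.5), latency = 0.4,
                               width = 0.09, fs = 256,
                               narrow_band = c(0.5, 15),
                               baseline_window = c(-0.1, 0)) {
  tt <- -0.1 + (0:(round(1.6 * fs) - 1)) / fs
  g <- exp(-(tt - latency)^2 / (2 * width^2))
  rec <- continuous_recording(matrix(g, 1), fs, "Pz")
  gf <- bandpass_iir(rec, narrow_band[1], narrow_band[2])$data[1, ]
  bl <- tt >= baseline_window[1] & tt < baseline_window[2]
  gf <- gf - mean(gf[bl])
  mean(gf[tt >= window[1] & tt < window[2]])
}

#' Ground-truth recovery study for the latency estimator
#'
#' Simulates speeded-condition epochs containing a single decision-locked
#' P3 with prescribed true peak latencies (uniform over `lat_range`) on
#' top of the default background noise, runs the standard chain (wide
#' band-pass, resample, EOG regression, continuous matching-band filter,
#' epoching) and the iterative template matcher initialised with
#' RT-coupled estimates (truth plus Gaussian jitter), and compares the
#' estimates with the injected truth.
#'
#' @param n_trials Number of trials (default 250).
#' @param seed Integer seed driving every random draw.
#' @param amplitude P3 peak amplitude in microvolt (default 8, on the
#'   order of the analysis-band background RMS).
#' @param width P3 Gaussian SD in seconds.
#' @param lat_range True-latency range in seconds.
#' @param init_jitter_sd SD (s) of the jitter between true latency and
#'   the RT used as the initial estimate.
#' @param montage_size Montage for the simulation (default the reduced
#'   9-channel set).
#' @param noise `TRUE` for the default background noise; `FALSE` for a
#'   noise-free run.
#' @param config A [woody_config()].
#' @return A list: `table` (`data.frame` with `true_s`, `est_s`,
#'   `flagged`), `r` (Pearson correlation), `mae_s` (mean absolute
#'   error), `max_err_samples` (worst error in samples at 256 Hz).
#' @export
p3_recovery_study <- function(n_trials = 250, seed = 1, amplitude = 8,
                              width = 0.09, lat_range = c(0.4, 0.8),
                              init_jitter_sd = 0.05, montage_size = 9,
                              noise = TRUE, config = woody_config()) {
  set.seed(seed)
  nb <- max(1, n_trials %/% 8)
  pairs <- generate_stimulus_list(n_total = n_trials, n_zero = nb,
                                  n_top = nb, seed = seed + 1)
  prof <- subject_profiles(1, "speeded", seed = seed + 2)
  prof$miss_rate <- 0
  beh <- simulate_behavior(pairs, prof, "speeded", seed = seed + 3)
  true_lat <- stats::runif(n_trials, lat_range[1], lat_range[2])
  beh$true_p3_s <- true_lat
  beh$rt_s <- true_lat + stats::rnorm(n_trials, 0, init_jitter_sd)
  ch <- default_montage(montage_size)
  p3 <- component_spec("P3", topo_posterior_left(ch),
                       latency = list(type = "column", column = "true_p3_s"),
                       waveform = list(shape = "gauss", width_s = width),
                       amplitude = list(type = "constant", base = amplitude))
  noise_model <- if (noise) {
    list(pink_rms = 4.5, pink_exponent = 1, alpha_rms = 8, alpha_freq = 10)
  } else {
    list(pink_rms = 0, pink_exponent = 1, alpha_rms = 0, alpha_freq = 10)
  }
  eog_model <- if (noise) {
    list(blink_rate = 0.1, blink_amp = 120, blink_width = 0.12,
         noise_rms = 3, propagation = NULL)
  } else {
    list(blink_rate = 0, blink_amp = 0, blink_width = 0.12, noise_rms = 0,
         propagation = NULL)
  }
  cfg <- simulation_config("speeded", channel_names = ch,
                           component_specs = list(p3), noise = noise_model,
                           eog = eog_model)
  sim <- simulate_eeg(beh, cfg, seed = seed + 4)
  rec <- bandpass_iir(sim$recording, 0.1, 50)
  rec <- resample_recording(rec, 256)
  rec <- regress_eog(rec)
  wep <- woody_epochs(rec, beh, config)
  lt <- estimate_latencies(wep, wep$trials$rt_s, config, prefilter = FALSE)
  est <- lt$latency_s[match(beh$trial_id, lt$trial_id)]
  err <- abs(est - true_lat)
  list(table = data.frame(true_s = true_lat, est_s = est,
                          flagged = lt$flagged[match(beh$trial_id,
                                                     lt$trial_id)]),
       r = stats::cor(est, true_lat),
       mae_s = mean(err),
       max_err_samples = max(err) * 256)
}
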