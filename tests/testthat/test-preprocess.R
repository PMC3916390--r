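make_rec <- function(x, fs = 256, events = NULL, names = "Cz") {
  continuous_recording(matrix(x, nrow = length(names), byrow = TRUE), fs,
                       names, events)
}

test_that("two-way filtering is zero-phase and blocks DC", {
  fs <- 256
  t <- (0:(8 * fs - 1)) / fs
  x <- sin(2 * pi * 10 * t)
  y <- bandpass_iir(make_rec(x, fs), 0.5, 15)$data[1, ]
  mid <- (2 * fs):(6 * fs)  # away from edges
  # peak latency shift < 1 sample: cross-correlation argmax at zero lag
  lags <- -3:3
  cc <- sapply(lags, function(l) cor(x[mid], y[mid + l]))
  expect_equal(lags[which.max(cc)], 0)
  ydc <- bandpass_iir(make_rec(rep(1, 8 * fs), fs), 0.5, 15)$data[1, ]
  expect_lt(max(abs(ydc[mid])), 0.01)
  expect_error(bandpass_iir(make_rec(x, fs), 0.5, 200), "Nyquist")
})

test_that("measured attenuation matches the squared one-pass response oracle", {
  fs <- 256
  t <- (0:(30 * fs - 1)) / fs
  bf <- signal::butter(3, c(0.5, 15) / (fs / 2), type = "pass")
  freqs <- c(0.5, 2, 8, 15)
  H <- signal::freqz(bf, n = freqs, Fs = fs)  # independent oracle
  for (k in seq_along(freqs)) {
    x <- sin(2 * pi * freqs[k] * t)
    y <- bandpass_iir(make_rec(x, fs), 0.5, 15)$data[1, ]
    mid <- (10 * fs):(20 * fs)
    meas <- sd(y[mid]) / sd(x[mid])
    expect_equal(meas, Mod(H$h[k])^2, tolerance = 0.05)
  }
})

test_that("integer-factor resampling agrees with analytic evaluation and remaps events", {
  fs <- 512
  t <- (0:(4 * fs - 1)) / fs
  x <- sin(2 * pi * 7 * t) + 0.5 * cos(2 * pi * 31 * t)
  ev <- data.frame(sample = 1025L, label = "target", trial_id = "t1")
  rec <- make_rec(x, fs, ev)
  out <- resample_recording(rec, 256)
  t2 <- (0:(ncol(out$data) - 1)) / 256
  expect_equal(out$data[1, ], sin(2 * pi * 7 * t2) + 0.5 * cos(2 * pi * 31 * t2),
               tolerance = 1e-10, ignore_attr = TRUE)
  # raw sample 1025 (1-based; 2.0 s) -> sample 513 at 256 Hz
  expect_equal(out$events$sample, 513L)
  # duration preserved within one output sample
  expect_lt(abs(ncol(out$data) / 256 - length(x) / fs), 1 / 256)
  expect_identical(resample_recording(rec, 512)$data, rec$data)
  expect_warning(resample_recording(rec, 1024), "upsampling")
})

test_that("EOG regression recovers known leakage and leaves clean channels alone", {
  set.seed(5)
  n <- 5000
  eog <- stats::filter(rnorm(n, sd = 40), rep(1, 20) / 20, circular = TRUE)
  eog <- as.numeric(eog)
  brain <- rnorm(n, sd = 5)
  clean <- rnorm(n, sd = 5)
  dat <- rbind(brain + 0.3 * eog, clean, eog)
  rec <- continuous_recording(dat, 256, c("Cz", "Pz", "EOG"))
  out <- regress_eog(rec, "EOG")
  expect_lt(abs(cor(out$data["Cz", ], eog)), 0.03)
  b <- out$log[[length(out$log)]]$coefficients
  expect_equal(unname(b["Cz", 1]), 0.3, tolerance = 0.02)
  expect_equal(out$data["Pz", ], dat[2, ], tolerance = 0.05,
               ignore_attr = TRUE)
  expect_identical(out$data["EOG", ], rec$data["EOG", ])
  # EEG channel that is an exact copy of EOG -> residual ~ 0 (up to mean)
  rec2 <- continuous_recording(rbind(eog, eog), 256, c("Cz", "EOG"))
  res <- regress_eog(rec2, "EOG")$data["Cz", ]
  expect_lt(sd(res), 1e-8)
  # zero-variance EOG is skipped with a warning
  rec3 <- continuous_recording(rbind(brain, rep(0, n)), 256, c("Cz", "EOG"))
  expect_warning(out3 <- regress_eog(rec3, "EOG"), "zero-variance")
  expect_identical(out3$data, rec3$data)
})

test_that("epoching uses half-open windows, drops boundary trials, and joins metadata", {
  fs <- 256
  n <- 6 * fs
  x <- numeric(n)
  ev_samples <- c(300L, 800L, n - 10L)  # last one too close to the end
  x[ev_samples] <- 1  # impulse at each lock sample
  ev <- data.frame(sample = ev_samples, label = "target",
                   trial_id = c("a", "b", "c"))
  md <- data.frame(trial_id = c("a", "b", "c"), as_score = c(5, 10, 1),
                   missed = FALSE)
  ep <- epoch_recording(make_rec(x, fs, ev), "target", metadata = md)
  expect_equal(dim(ep$data)[3], round(1.6 * 256))
  expect_equal(dim(ep$data)[1], 2)
  expect_equal(ep$drop_log$trial_id, "c")
  expect_equal(ep$trials$as_score, c(5, 10))
  # the impulse sits at the t = 0 sample: index round(0.1*256) + 1
  for (k in 1:2) expect_equal(which(ep$data[k, 1, ] == 1), round(0.1 * 256) + 1)
  expect_error(epoch_recording(make_rec(x, fs, ev), "nope"), "no events")
})

test_that("baseline correction zeroes the window mean, exactly on ramps", {
  fs <- 256
  ep <- make_bump_epochs(lat = c(0.4, 0.6), amp = 3)
  ep$data[1, 1, ] <- ep$data[1, 1, ] + 7           # constant offset
  tt <- epoch_times(ep)
  ep$data[2, 1, ] <- 2 * tt                         # pure ramp
  out <- baseline_correct(ep)
  sel <- tt >= -0.1 & tt < 0
  for (k in 1:2) expect_lt(abs(mean(out$data[k, 1, sel])), 1e-12)
  # ramp: output = input minus the analytic window mean
  expect_equal(out$data[2, 1, ], 2 * tt - mean(2 * tt[sel]),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(baseline_correct(ep, c(0.9, 0.9)), "empty")
})

test_that("no-response rejection keeps exact counts", {
  n <- 8000
  dat <- array(0, c(n, 1, 2))
  missed <- rep(FALSE, n); missed[sample.int(n, 241)] <- TRUE
  ep <- epoch_set(dat, -0.1, 256, "Pz", "stimulus",
                  trials = data.frame(trial_id = as.character(seq_len(n)),
                                      missed = missed))
  out <- reject_no_response(ep)
  expect_equal(dim(out$data)[1], 7759)
  lg <- out$log[[length(out$log)]]
  expect_equal(lg$n_rejected, 241)
  ep0 <- subset_epochs(ep, !missed)
  expect_equal(dim(reject_no_response(ep0)$data)[1], 7759)  # identity
  ep_all <- subset_epochs(ep, missed)
  expect_warning(out_all <- reject_no_response(ep_all), "all trials")
  expect_equal(dim(out_all$data)[1], 0)
})

test_that("the filtering chain is linear", {
  set.seed(6)
  x <- rnorm(2000)
  r1 <- bandpass_iir(make_rec(x), 0.5, 15)$data[1, ]
  r3 <- bandpass_iir(make_rec(3 * x), 0.5, 15)$data[1, ]
  expect_equal(r3, 3 * r1, tolerance = 1e-7)
})
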