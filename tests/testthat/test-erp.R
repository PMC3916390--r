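fake_meta <- function(n, as = NULL, rt = NULL, resp = NULL) {
  data.frame(trial_id = sprintf("t%04d", seq_len(n)),
             as_score = as %||% rep(1, n), rt_s = rt %||% rep(0.5, n),
             response = resp %||% rep("related", n),
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("binning yields contiguous equal-size blocks with the Table-1 orientation", {
  md <- fake_meta(800, as = sample(0:95, 800, replace = TRUE),
                  rt = runif(800, 0.3, 0.9))
  b <- bin_trials(md, "as", 8)
  expect_true(all(b$summary$n == 100))
  expect_true(all(diff(b$summary$mean_as) < 0))  # bin 1 = highest AS
  brt <- bin_trials(md, "rt", 8)
  expect_true(all(diff(brt$summary$mean_rt) > 0))  # bin 1 = fastest
  # sizes differ by at most one; remainder goes to low-index bins
  b10 <- bin_trials(fake_meta(10, as = 1:10), "as", 8)
  expect_equal(b10$summary$n, c(2, 2, 1, 1, 1, 1, 1, 1))
  expect_equal(b10$remainder, 2L)
  expect_error(bin_trials(fake_meta(5), "as", 8), "exceeds")
  md_na <- fake_meta(10); md_na$rt_s[3] <- NA
  expect_error(bin_trials(md_na, "rt"), "non-finite")
})

test_that("binning is a stable sort with trial_id tie-break", {
  md <- fake_meta(6, as = c(5, 5, 5, 2, 2, 2))
  b <- bin_trials(md, "as", 2)
  expect_equal(b$assignment$trial_id[b$assignment$bin == 1],
               sprintf("t%04d", 1:3))
})

test_that("averaging is linear: identical trials, cancellation, grand average", {
  ep <- make_bump_epochs(lat = rep(0.5, 4), amp = 2)
  asg <- bin_trials(fake_meta(4), "as", 1)
  erp <- average_erp(ep, asg)
  expect_equal(erp$waveforms[1, 1, ], ep$data[1, 1, ], ignore_attr = TRUE)
  ep2 <- ep; ep2$data[2, 1, ] <- -ep2$data[1, 1, ]
  ep2$data[4, 1, ] <- -ep2$data[3, 1, ]
  erp2 <- average_erp(ep2, asg)
  expect_lt(max(abs(erp2$waveforms)), 1e-12)
  # grand average is the unweighted subject mean
  g <- grand_average(list(erp, erp2))
  expect_equal(g$waveforms, (erp$waveforms + erp2$waveforms) / 2)
  expect_equal(g$level, "grand")
  # empty bin errors
  asg8 <- bin_trials(fake_meta(4), "as", 2)
  asg8$assignment$bin <- 1L
  expect_error(average_erp(ep, asg8), "bin 2")
})

test_that("ERP RMS shrinks like 1/sqrt(n) on noise-only epochs", {
  set.seed(7)
  n_tr <- 100
  ep <- make_bump_epochs(lat = rep(0.5, n_tr), amp = 0,
                         noise_fun = function(n) rnorm(n))
  erp <- average_erp(ep, bin_trials(fake_meta(n_tr), "as", 1))
  ratio <- sd(erp$waveforms[1, 1, ]) / mean(apply(ep$data[, 1, ], 1, sd))
  expect_gt(ratio, 0.07); expect_lt(ratio, 0.14)  # expected 0.1
})

test_that("response relocking aligns and sharpens an RT-coupled component", {
  fs <- 256
  rt <- runif(40, 0.45, 0.85)
  ep <- make_bump_epochs(lat = rt, amp = 1, rt = rt)
  rl <- relock_to_response(ep)
  expect_equal(rl$t0, -0.5)
  expect_equal(dim(rl$data)[3], round(1.0 * fs))
  # trial with response exactly at +0.5 s: relocked t=0 equals source 0.5 s
  i <- which.min(abs(rt - 0.5))
  src_idx <- round((rt[i] + 0.1) * fs) + 1
  rel_idx <- round(0.5 * fs) + 1
  expect_equal(rl$data[i, 1, rel_idx], ep$data[i, 1, src_idx])
  # response-locked mean is sharper than the stimulus-locked mean
  stim_mean <- apply(ep$data[, 1, ], 2, mean)
  resp_mean <- apply(rl$data[, 1, ], 2, mean)
  expect_gt(max(resp_mean), max(stim_mean) + 0.1)
  # missing response onsets are dropped and logged
  ep$trials$rt_s[3] <- NA
  rl2 <- relock_to_response(ep)
  expect_equal(dim(rl2$data)[1], 39)
  expect_true("t0003" %in% rl2$drop_log$trial_id)
})

test_that("windowed mean amplitude matches closed forms", {
  ep <- make_bump_epochs(lat = c(0.5, 0.5), amp = 0)
  ep$data[1, 1, ] <- 5
  tt <- epoch_times(ep)
  ep$data[2, 1, ] <- (tt - 0.3) / 0.2  # ramp 0 -> 1 over the window
  v <- mean_amplitude(ep, "Pz", c(0.3, 0.5))
  expect_equal(v[1], 5)
  expect_equal(v[2], 0.5, tolerance = 0.01)  # half-sample tolerance
  expect_error(mean_amplitude(ep, "Pz", c(2, 3)), "outside")
  expect_error(mean_amplitude(ep, "Oz", c(0.3, 0.5)), "not present")
})

test_that("topography snapshots reproduce injected gain patterns", {
  w <- array(0, c(2, 3, 10))
  topo <- c(0.5, 1, 0.25)
  for (k in 1:10) w[1, , k] <- topo * exp(-((k - 5) / 2)^2)
  erp <- structure(list(waveforms = w, t0 = 0, sfreq = 10,
                        channel_names = c("Cz", "Pz", "Oz"),
                        lock = "stimulus", n_trials = c(1, 1),
                        level = "subject"), class = "erp_set")
  snap <- topography(erp, 0.4, bin = 1)
  expect_equal(unname(snap / snap["Pz"]), topo)
  expect_equal(unname(topography(erp, 0.4, bin = 1, minus_bin = 1)),
               rep(0, 3))
  expect_error(topography(erp, 5), "outside")
})

test_that("grand averaging commutes with channel selection and window means", {
  set.seed(8)
  mk <- function() {
    ep <- make_bump_epochs(lat = runif(6, 0.3, 0.7), amp = 2,
                           noise_fun = function(n) rnorm(n, sd = 0.1))
    average_erp(ep, bin_trials(fake_meta(6), "as", 2))
  }
  e1 <- mk(); e2 <- mk()
  g <- grand_average(list(e1, e2))
  m_g <- mean_amplitude(g, "Pz", c(0.3, 0.5))
  m_each <- (mean_amplitude(e1, "Pz", c(0.3, 0.5)) +
             mean_amplitude(e2, "Pz", c(0.3, 0.5))) / 2
  expect_equal(m_g, m_each)
})
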