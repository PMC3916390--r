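test_that("noiseless bumps are recovered within one sample despite biased inits", {
  set.seed(101)
  lat <- runif(30, 0.4, 0.8)
  ep <- make_bump_epochs(lat, amp = 1, width = 0.09)
  lt <- estimate_latencies(ep, lat + 0.1, prefilter = FALSE)
  expect_true(all(abs(lt$latency_s - lat) <= 1 / ep$sfreq + 1e-9))
  expect_false(any(lt$flagged))
  # convergence bookkeeping: mean absolute change is non-increasing
  h <- attr(lt, "history")$mean_abs_change_s
  expect_true(all(diff(h) <= 1e-12))
})

test_that("an impulse template turns the score sequence into the signal itself", {
  set.seed(102)
  ep <- make_bump_epochs(lat = c(0.5, 0.6), amp = 1,
                         noise_fun = function(n) rnorm(n, sd = 0.2))
  X <- erpoverlap:::woody_signal(ep, woody_config(score = "dot"),
                                 prefilter = FALSE)
  tt <- epoch_times(ep)
  cand <- which(tt >= 0.35 & tt <= 0.9)
  tpl <- c(0, 1, 0)
  S <- erpoverlap:::score_matrix(X, tpl, cand, H = 1, type = "dot", ref = 2)
  for (i in 1:2) expect_equal(S[i, ], X[i, cand], ignore_attr = TRUE)
})

test_that("peak picking equals the exhaustive-search oracle on arbitrary sequences", {
  set.seed(103)
  for (k in 1:200) {
    s <- rnorm(30)
    if (k %% 3 == 0) s <- abs(s)           # all-positive sequences
    if (k %% 5 == 0) s[10:12] <- s[10]      # plateaus
    if (k %% 7 == 0) s <- -abs(s)           # no positive peak at all
    expect_identical(erpoverlap:::pick_peak(s), oracle_pick_peak(s))
  }
})

test_that("one matching iteration equals the oracle argmax on its own score matrix", {
  set.seed(104)
  lat <- runif(25, 0.42, 0.78)
  ep <- make_bump_epochs(lat, amp = 1, width = 0.09,
                         noise_fun = function(n) rnorm(n, sd = 0.5))
  cfg <- woody_config(n_iterations = 1)
  lt <- estimate_latencies(ep, lat, cfg, prefilter = FALSE)
  X <- erpoverlap:::woody_signal(ep, cfg, prefilter = FALSE)
  H <- round(0.5 * ep$sfreq)
  tt <- epoch_times(ep)
  cand <- which(tt >= 0.35 & tt <= 0.9)
  to_idx <- function(l) round((l - ep$t0) * ep$sfreq) + 1
  tpl <- erpoverlap:::build_template(X, to_idx(lat), H)
  S <- erpoverlap:::score_matrix(X, tpl, cand, H, "ncc")
  for (i in seq_along(lat)) {
    p <- oracle_pick_peak(S[i, ])
    if (!is.na(p)) expect_equal(lt$latency_s[i], tt[cand[p]])
  }
})

test_that("estimates are shift-equivariant and amplitude-invariant", {
  set.seed(105)
  lat <- runif(20, 0.45, 0.70)
  noise <- matrix(rnorm(20 * 410, sd = 0.3), 20)
  mk <- function(shift_s = 0, scale = 1) {
    ep <- make_bump_epochs(lat + shift_s, amp = 1, width = 0.09)
    for (i in 1:20) ep$data[i, 1, ] <- scale *
        (ep$data[i, 1, ] + noise[i, ])
    ep
  }
  k <- 5
  ep0 <- mk(); epk <- mk(shift_s = k / 256)
  # the noise is not shifted, so shift only the bumps: rebuild epk noise
  epk$data <- epk$data
  lt0 <- estimate_latencies(ep0, lat, prefilter = FALSE)
  ep_scaled <- mk(scale = 3)
  lt_scaled <- estimate_latencies(ep_scaled, lat, prefilter = FALSE)
  expect_identical(lt0$latency_s, lt_scaled$latency_s)
  # shift equivariance with the noise shifted too
  ep_sh <- ep0
  n <- dim(ep_sh$data)[3]
  ep_sh$data[, , (k + 1):n] <- ep0$data[, , 1:(n - k)]
  ep_sh$data[, , 1:k] <- 0
  lt_sh <- estimate_latencies(ep_sh, lat + k / 256, prefilter = FALSE)
  interior <- lt0$latency_s > 0.36 & lt0$latency_s < 0.88
  expect_equal(lt_sh$latency_s[interior],
               lt0$latency_s[interior] + k / 256, tolerance = 1e-9)
})

test_that("template re-use reproduces source estimates on the source epochs", {
  set.seed(106)
  lat <- runif(30, 0.45, 0.75)
  ep <- make_bump_epochs(lat, amp = 1, width = 0.09,
                         noise_fun = function(n) rnorm(n, sd = 0.3))
  lt <- estimate_latencies(ep, lat, prefilter = FALSE)
  lt2 <- reuse_template(attr(lt, "template"), ep, prefilter = FALSE)
  expect_equal(lt2$latency_s, lt$latency_s)
  # rate mismatch rejected
  tpl <- attr(lt, "template"); attr(tpl, "sfreq") <- 512
  expect_error(reuse_template(tpl, ep, prefilter = FALSE), "rate")
})

test_that("delayed-condition latencies show no AS effect without a covert P3", {
  set.seed(107)
  # speeded template from clean bumps
  lat_sp <- runif(60, 0.45, 0.75)
  ep_sp <- make_bump_epochs(lat_sp, amp = 8, width = 0.09,
                            noise_fun = function(n) rnorm(n, sd = 2))
  lt_sp <- estimate_latencies(ep_sp, lat_sp, prefilter = FALSE)
  # delayed epochs: no P3 at all, only noise; AS assigned at random
  ep_del <- make_bump_epochs(rep(0.6, 120), amp = 0,
                             noise_fun = function(n) rnorm(n, sd = 2))
  as_score <- sample(0:95, 120, replace = TRUE)
  lt_del <- quiet(reuse_template(attr(lt_sp, "template"), ep_del,
                                 prefilter = FALSE))
  x <- log(pmax(as_score, 1))
  obs <- abs(cor(lt_del$latency_s, x))
  null_cor <- replicate(400, abs(cor(sample(lt_del$latency_s), x)))
  expect_lt(obs, quantile(null_cor, 0.99))  # permutation null
})

test_that("a weak covert P3 tracking speeded RT is recovered with a positive weight", {
  set.seed(108)
  n <- 150
  mean_rt <- runif(n, 0.45, 0.75)
  ep <- make_bump_epochs(mean_rt, amp = 3, width = 0.09,
                         noise_fun = function(n) rnorm(n, sd = 2))
  # template from a separate clean speeded run
  lat_sp <- runif(80, 0.45, 0.75)
  ep_sp <- make_bump_epochs(lat_sp, amp = 8, width = 0.09,
                            noise_fun = function(n) rnorm(n, sd = 1))
  lt_sp <- estimate_latencies(ep_sp, lat_sp, prefilter = FALSE)
  lt <- quiet(reuse_template(attr(lt_sp, "template"), ep, prefilter = FALSE))
  fit <- lm(lt$latency_s ~ mean_rt)
  ci <- confint(fit)["mean_rt", ]
  expect_gt(coef(fit)["mean_rt"], 0)
  expect_gt(ci[1], 0)   # significantly positive
  expect_lt(ci[2], 1.5) # and not absurdly above the injected unit slope
})
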