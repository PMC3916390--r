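fake_trials <- function(n, subject = "S01", as = NULL, rt = NULL,
                        lat = NULL, prefix = "sp") {
  data.frame(trial_id = sprintf("%s_%s_%04d", prefix, subject, seq_len(n)),
             subject_id = subject,
             pair_id = sprintf("pair%04d", seq_len(n)),
             as_score = as %||% rep(1, n),
             rt_s = rt %||% rep(0.65, n),
             latency_s = lat %||% rep(0.65, n),
             missed = FALSE, stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the matching score is an L1 discrepancy with exact-match zero", {
  expect_equal(match_score(0.65, 0.65), 0)
  expect_equal(match_score(0.75, 0.65), 0.1)
  expect_equal(match_score(0.65, 0.55), 0.1)
  # symmetric in the two terms
  expect_equal(match_score(0.70, 0.60), match_score(0.60, 0.70))
  # ranking equals an independently coded L1 oracle
  set.seed(201)
  rt <- runif(50, 0.3, 1); p3 <- runif(50, 0.35, 0.9)
  oracle <- abs(rt - 0.65) + abs(p3 - 0.65)
  expect_equal(order(match_score(rt, p3)), order(oracle))
})

test_that("competition groups enforce equal sizes and delayed-condition matching", {
  set.seed(202)
  sp <- rbind(
    fake_trials(40, as = 0, lat = runif(40, 0.38, 0.50)),
    fake_trials(60, as = 50, lat = runif(60, 0.60, 0.80)))
  sp$pair_id <- sprintf("pair%04d", seq_len(nrow(sp)))
  sp$trial_id <- paste0("sp_", sp$pair_id)
  del <- sp; del$trial_id <- paste0("del_", del$pair_id)
  g <- build_competition_groups(sp, del, seed = 1)
  expect_equal(as.vector(table(g$group)), rep(40L, 4))
  # delayed members correspond by (subject, pair)
  for (k in 1:2) {
    ks <- g[g$group == k, ]; kd <- g[g$group == k + 2, ]
    expect_equal(ks$pair_id, kd$pair_id)
    expect_true(all(startsWith(kd$trial_id, "del_")))
  }
  # groups are disjoint at trial level
  expect_false(any(duplicated(g$trial_id)))
  # a combination absent in the delayed condition leaves all sizes equal
  del2 <- del[del$pair_id != g$pair_id[g$group == 1][1], ]
  g2 <- build_competition_groups(sp, del2, seed = 1)
  expect_equal(length(unique(table(g2$group))), 1L)
  expect_false(g$pair_id[g$group == 1][1] %in% g2$pair_id)
  # empty selections are reported by criterion
  expect_error(build_competition_groups(sp, del, p3_short_max = 0.1,
                                        seed = 1), "latency <= 0.1")
})

test_that("fixed-latency matching with a perfect duplicate pool pairs at score zero", {
  lowrt <- seq(0.60, 0.70, length.out = 10)
  lowlat <- seq(0.62, 0.68, length.out = 10)
  low <- fake_trials(10, as = 0, rt = lowrt, lat = lowlat)
  high <- fake_trials(10, as = 50, rt = lowrt, lat = lowlat)
  high$trial_id <- paste0("hi_", high$trial_id)
  high$pair_id <- paste0("hp", seq_len(10))
  g <- build_fixed_latency_groups(rbind(low, high), n_per_subject = 10)
  expect_equal(sum(g$group == "lowAS"), 10)
  expect_equal(sum(g$group == "highAS"), 10)
  hi <- g[g$group == "highAS", ]
  expect_true(all(hi$score == 0))
  lo_rt <- low$rt_s[match(g$trial_id[g$group == "lowAS"], low$trial_id)]
  hi_rt <- high$rt_s[match(hi$trial_id, high$trial_id)]
  expect_equal(mean(lo_rt) - mean(hi_rt), 0)
})

test_that("fixed-latency matching balances RT and latency on random pools", {
  set.seed(203)
  rows <- list()
  for (s in sprintf("S%02d", 1:3)) {
    low <- fake_trials(120, subject = s, as = 0,
                       rt = rnorm(120, 0.67, 0.12),
                       lat = rnorm(120, 0.67, 0.12))
    high <- fake_trials(300, subject = s, as = 50,
                        rt = rnorm(300, 0.55, 0.12),
                        lat = rnorm(300, 0.55, 0.12))
    high$trial_id <- paste0("hi_", high$trial_id)
    rows[[s]] <- rbind(low, high)
  }
  tr <- do.call(rbind, rows)
  g <- build_fixed_latency_groups(tr, n_per_subject = 75)
  expect_equal(sum(g$group == "lowAS"), 225)
  lo <- tr[match(g$trial_id[g$group == "lowAS"], tr$trial_id), ]
  hi <- tr[match(g$trial_id[g$group == "highAS"], tr$trial_id), ]
  expect_lt(abs(mean(lo$rt_s) - mean(hi$rt_s)), 0.02)
  expect_lt(abs(mean(lo$latency_s) - mean(hi$latency_s)), 0.02)
  # 1:1 without replacement
  expect_false(any(duplicated(g$trial_id)))
  # shortfall reported per subject
  expect_error(build_fixed_latency_groups(tr, n_per_subject = 500),
               "S01")
})

test_that("matching is stable under row permutation and improves with pool size", {
  set.seed(204)
  low <- fake_trials(40, as = 0, rt = rnorm(40, 0.65, 0.1),
                     lat = rnorm(40, 0.65, 0.1))
  big <- fake_trials(200, as = 50, rt = rnorm(200, 0.55, 0.15),
                     lat = rnorm(200, 0.55, 0.15))
  big$trial_id <- paste0("hi_", big$trial_id)
  tr <- rbind(low, big)
  g1 <- build_fixed_latency_groups(tr, n_per_subject = 30)
  g2 <- build_fixed_latency_groups(tr[sample(nrow(tr)), ], n_per_subject = 30)
  expect_equal(sort(g1$trial_id), sort(g2$trial_id))
  # growing the high pool cannot worsen the mean pairing score
  small <- rbind(low, big[1:60, ])
  gs <- build_fixed_latency_groups(small, n_per_subject = 30)
  msc <- function(g) mean(g$score[g$group == "highAS"])
  expect_lte(msc(g1), msc(gs))
})

test_that("group contrasts report zero difference for identical groups", {
  set.seed(205)
  ep <- make_bump_epochs(lat = rep(0.45, 40), amp = 2,
                         noise_fun = function(n) rnorm(n, sd = 0.5))
  ep$trials$subject_id <- rep(sprintf("S%02d", 1:4), each = 10)
  ep$trials$pair_id <- rep(sprintf("p%02d", 1:10), times = 4)
  asg <- data.frame(group = rep(c("A", "B"), each = 40),
                    trial_id = rep(ep$trials$trial_id, 2))
  res <- quiet(contrast_groups(ep, asg, groups = c("A", "B"),
                               channel = "Pz", window = c(0.4, 0.5)))
  expect_equal(res$difference, 0)
  expect_lt(abs(res$lme$t), 1e-6)
})
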