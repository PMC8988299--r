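p0 <- scoring_params(speed_threshold = 1)

test_that("immobility detection thresholds, bridges spikes, filters bouts", {
  still <- signal_trace(numeric(3000), 300)
  expect_equal(detect_immobility(still, p0), intervals(0, 10))

  # square wave: 10 s still / 10 s moving over 100 s -> five 10 s bouts
  sq <- signal_trace(rep(rep(c(0, 5), each = 3000), 5), 300)
  imm <- detect_immobility(sq, p0)
  expect_equal(nrow(imm), 5)
  expect_equal(imm$end - imm$start, rep(10, 5))

  # a single 0.1 s spike is bridged by the 0.2 s gap rule
  v <- numeric(6000); v[3000:3029] <- 5
  expect_equal(detect_immobility(signal_trace(v, 300), p0), intervals(0, 20))

  # raising the threshold never decreases immobility
  set.seed(4)
  sp <- signal_trace(abs(rnorm(6000)), 300)
  d <- vapply(c(0.5, 1, 2, 4), function(th) {
    interval_duration(detect_immobility(sp, scoring_params(speed_threshold = th)))
  }, numeric(1))
  expect_true(all(diff(d) >= 0))
})

test_that("SWS detection recovers the sleep half of a freeze/sleep session", {
  ses <- freeze_sleep_session()
  p <- default_test_params()
  cort <- decimate_lfp(ses$cortical, p$analysis_rate)
  imm <- detect_immobility(ses$speed, p)
  res <- detect_sws(cort, imm, p)
  sws_2nd <- interval_duration(interval_intersect(res$sws, intervals(300, 600)))
  sws_1st <- interval_duration(interval_intersect(res$sws, intervals(0, 300)))
  expect_gte(sws_2nd / 300, 0.9)
  expect_lte(sws_1st / 300, 0.05)
  expect_s3_class(res$threshold, "threshold_result")
  expect_gte(res$threshold$effectiveness, 0.5)

  # spindle-free noise: no sleep declared, warning not error
  set.seed(8)
  noise <- signal_trace(rnorm(250 * 120, 0, 0.2), 250)
  imm_all <- intervals(0, 120)
  expect_warning(res0 <- detect_sws(noise, imm_all, p), "no usable bimodality")
  expect_equal(nrow(res0$sws), 0)
})

test_that("supra-threshold bouts below the SWS minimum duration are removed", {
  # a brief spindle patch inside a long immobile session: detected under the
  # default 30 s minimum, wiped by a minimum above the patch's supra time
  p <- default_test_params()
  plan <- state_plan(c("freezing", "sws", "freezing"), c(240, 25, 240),
                     physiological = FALSE)
  ses <- generate_session(plan, seed = 19)
  cort <- decimate_lfp(ses$cortical, p$analysis_rate)
  imm <- detect_immobility(ses$speed, p)
  res <- suppressWarnings(detect_sws(cort, imm, p))
  supra_dur <- interval_duration(res$sws)
  expect_gt(supra_dur, 0)
  p60 <- p; p60$sws_min_duration <- supra_dur + 10
  res60 <- suppressWarnings(detect_sws(cort, imm, p60))
  expect_equal(interval_duration(res60$sws), 0)
})

test_that("REM requires a supra-threshold ratio and a preceding SWS anchor", {
  # interval-level rule checks on a constructed ratio trace (hpc mode)
  p <- p0
  rate <- 250; dur <- 300
  t <- (0:(dur * rate - 1)) / rate
  # theta-dominated segment [100, 160): REM candidate
  lfp <- sin(2 * pi * 7.5 * t) * (t >= 100 & t < 160) +
    sin(2 * pi * 2 * t) * (t < 100 | t >= 160) + rnorm(length(t), 0, 0.1)
  lfp <- signal_trace(lfp, rate)
  imm <- intervals(0, 300)
  sws <- intervals(0, 90)   # candidate starts 10 s after SWS ends
  rem <- detect_rem(lfp, imm, sws, p, mode = "hpc")
  expect_gt(interval_duration(interval_intersect(rem$rem, intervals(100, 160))),
            50)
  # no SWS anywhere -> no REM
  rem0 <- detect_rem(lfp, imm, empty_intervals(), p, mode = "hpc")
  expect_equal(nrow(rem0$rem), 0)
  # SWS too far in the past -> candidate dropped
  rem_far <- detect_rem(lfp, imm, intervals(0, 60), p, mode = "hpc")
  expect_equal(nrow(rem_far$rem), 0)
  # delta-dominated epoch after SWS stays non-REM
  lfp_delta <- signal_trace(sin(2 * pi * 2 * t) + rnorm(length(t), 0, 0.1), rate)
  rem_d <- detect_rem(lfp_delta, imm, sws, p, mode = "hpc")
  expect_equal(nrow(rem_d$rem), 0)
})

test_that("quiet wakefulness precedes SWS within the lead window", {
  imm <- intervals(c(0, 100, 400), c(50, 160, 500))
  sws <- intervals(220, 380)
  qw <- detect_quiet_wake(imm, sws, empty_intervals(), p0)
  # bout ending 60 s before SWS onset kept; bout ending 170 s before dropped
  expect_equal(qw, intervals(100, 160))
  expect_equal(nrow(detect_quiet_wake(imm, empty_intervals(), empty_intervals(), p0)), 0)
})

test_that("freezing is the filtered remainder of immobility", {
  imm <- intervals(0, 100)
  none <- empty_intervals()
  # no sleep: all immobility >= 2 s becomes freezing
  expect_equal(detect_freezing(imm, none, none, none, p0), imm)
  # 1.5 s fragment dropped
  imm2 <- intervals(c(0, 50), c(1.5, 60))
  expect_equal(detect_freezing(imm2, none, none, none, p0), intervals(50, 60))
  # 0.1 s gap bridged
  imm3 <- intervals(c(0, 5.1), c(5, 9))
  expect_equal(detect_freezing(imm3, none, none, none, p0), intervals(0, 9))
  # gap-closing never swallows time claimed by other states
  sws <- intervals(30, 70)
  frz <- detect_freezing(intervals(0, 100), sws, none, none, p0)
  expect_equal(interval_duration(interval_intersect(frz, sws)), 0)
})

test_that("full scoring recovers a planned session and keeps states disjoint", {
  plan <- state_plan(
    c("active", "freezing", "active", "quiet_wake", "sws", "rem", "sws", "active"),
    c(60, 120, 120, 60, 240, 60, 120, 60)
  )
  ses <- generate_session(plan, seed = 21)
  sc <- score_session(ses$cortical, ses$speed, hpc = ses$hpc)
  expect_s3_class(sc, "state_scoring")
  expect_equal(sc$diagnostics$mode, "hpc")
  ag <- scoring_agreement(sc, ses$truth)
  expect_gte(ag$agreement, 0.9)
  expect_equal(total_state_overlap(sc), 0)
  for (s in c("sws", "rem", "quiet_wake", "freezing")) {
    outside <- interval_subtract(sc[[s]], sc$immobility)
    expect_lte(interval_duration(outside), 2 / 250)
  }
  # determinism: identical inputs give identical scorings
  sc2 <- score_session(ses$cortical, ses$speed, hpc = ses$hpc)
  expect_identical(tidy(sc), tidy(sc2))
})

test_that("an all-moving session yields four empty state sets", {
  ses <- generate_session(state_plan("active", 120), seed = 33)
  sc <- suppressWarnings(
    score_session(ses$cortical, ses$speed, hpc = ses$hpc,
                  params = default_test_params())
  )
  for (s in c("sws", "rem", "quiet_wake", "freezing")) {
    expect_equal(nrow(sc[[s]]), 0)
  }
})

test_that("a sleep-only session has no freezing and near-complete coverage", {
  plan <- state_plan(c("active", "quiet_wake", "sws", "rem", "sws", "active"),
                     c(60, 60, 240, 60, 120, 30))
  ses <- generate_session(plan, seed = 34)
  sc <- score_session(ses$cortical, ses$speed, hpc = ses$hpc)
  expect_equal(interval_duration(sc$freezing), 0)
  covered <- interval_duration(sc$sws) + interval_duration(sc$rem) +
    interval_duration(sc$quiet_wake)
  expect_gte(covered / interval_duration(sc$immobility), 0.9)
})

test_that("misaligned traces are rejected", {
  ses <- generate_session(state_plan("active", 60), seed = 1)
  short_speed <- signal_trace(ses$speed$samples[1:(300 * 30)], 300)
  expect_error(score_session(ses$cortical, short_speed),
               class = "spindlescore_alignment_error")
})

test_that("the standard scorer reproduces the freezing/sleep confound", {
  plan <- state_plan(c("active", "freezing", "active", "freezing"),
                     c(60, 300, 60, 300))
  ses <- generate_session(plan, seed = 7)
  params <- default_test_params()
  std <- standard_score(ses$hpc, ses$speed, params = params)
  frz_true <- ses$truth[ses$truth$state == "freezing", c("start", "end")]
  sleep_on_frz <- interval_duration(interval_intersect(std$sleep, frz_true))
  expect_gt(sleep_on_frz / interval_duration(frz_true), 0.5)
  expect_gt(interval_duration(std$overlap), 0)

  sc <- suppressWarnings(score_session(ses$cortical, ses$speed, hpc = ses$hpc,
                                       params = params))
  sws_on_frz <- interval_duration(interval_intersect(sc$sws, frz_true))
  expect_lt(sws_on_frz / interval_duration(frz_true), 0.05)

  # 1.4 s immobility bout is excluded from standard freezing
  v <- rep(5, 3000); v[301:720] <- 0   # 1.4 s still at 300 Hz
  spd <- signal_trace(v, 300)
  std2 <- standard_score(ses$hpc, spd, params = params)
  expect_equal(nrow(std2$freezing), 0)
})

test_that("standard and proposed SWS agree on a sleep session", {
  plan <- state_plan(c("active", "quiet_wake", "sws", "active"),
                     c(30, 90, 300, 30))
  ses <- generate_session(plan, seed = 44)
  params <- default_test_params()
  std <- standard_score(ses$hpc, ses$speed, params = params)
  sc <- score_session(ses$cortical, ses$speed, hpc = ses$hpc, params = params)
  sleep_true <- ses$truth[ses$truth$state == "sws", c("start", "end")]
  both <- interval_duration(interval_intersect(std$sleep, sc$sws))
  expect_gte(both / interval_duration(sleep_true), 0.8)
})

test_that("tidy, glance, and autoplot work on scored sessions", {
  plan <- state_plan(c("active", "quiet_wake", "sws", "active"), c(30, 60, 200, 30))
  ses <- generate_session(plan, seed = 13)
  sc <- score_session(ses$cortical, ses$speed, hpc = ses$hpc)
  td <- tidy(sc)
  expect_true(all(c("start", "end", "duration", "state") %in% names(td)))
  expect_true(all(td$duration > 0))
  gl <- glance(sc)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$mode, "hpc")
  expect_gt(gl$sws_s, 100)
  pl <- ggplot2::autoplot(sc)
  expect_s3_class(pl, "ggplot")
})
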