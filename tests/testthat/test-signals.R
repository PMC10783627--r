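test_that("trailing running average matches its closed form on a step", {
  tr <- signal_trace(c(rep(10, 60), rep(0, 60)), fs = 1000, units = "mV")
  sm <- smooth_running_average(tr, 27)
  expect_equal(length(sm$values), length(tr$values))
  expect_equal(attr(sm, "smooth_samples"), 27L)
  # constant region before the step is untouched (after warm-up it is the
  # mean of identical values; at the very first sample it is the raw value)
  expect_equal(sm$values[1], 10)
  expect_equal(sm$values[40], 10)
  # step 10 -> 0 at sample 61: value at 61 + j is 10 * (26 - j) / 27
  s <- 61
  for (j in c(0, 1, 10, 26)) {
    expect_equal(sm$values[s + j], 10 * (26 - j) / 27)
  }
  expect_equal(sm$values[s + 27], 0)
  # agrees with the naive oracle everywhere
  expect_equal(sm$values, oracle_smooth(tr$values, 27))
})

test_that("running average preserves constants and units, errors on overlong windows", {
  tr <- signal_trace(rep(42, 100), fs = 1000, units = "mN")
  sm <- smooth_running_average(tr, 27)
  expect_equal(sm$values, rep(42, 100))
  expect_equal(sm$units, "mN")
  expect_error(smooth_running_average(signal_trace(1:5, units = "mV"), 27),
               "window exceeds trace")
})

test_that("running average realizes whole-sample windows at non-1kHz rates", {
  tr <- signal_trace(rep(1, 100), fs = 200, units = "px")
  sm <- smooth_running_average(tr, 27) # 27 ms at 200 Hz -> 5 samples
  expect_equal(attr(sm, "smooth_samples"), 5L)
  expect_equal(attr(sm, "smooth_window_ms"), 25)
})

test_that("baseline level is the pre-onset epoch mean", {
  tr <- signal_trace(rep(100, 1200), fs = 1000, units = "mV")
  expect_equal(baseline_level(tr, onset = 600, window = 500), 100)
  # linear ramp 0 -> 100 over the 500 ms baseline window: mean ~ 50
  ramp <- c(seq(0, 100, length.out = 500), rep(100, 200))
  tr2 <- signal_trace(ramp, fs = 1000, units = "mV")
  expect_equal(baseline_level(tr2, onset = 500, window = 500), 50,
               tolerance = 1e-6)
  expect_error(baseline_level(tr, onset = 0, window = 500),
               "baseline window not covered")
})

test_that("reflectance detector recovers a smoothed step crossing exactly", {
  # noiseless step drop of 5 mV at onset + 100 ms; with a 27-sample trailing
  # window the smoothed deficit is 5 (j + 1) / 27, first > 2 mV at j = 10
  stim <- stimulus_event("optogenetic", "pulse", onset = 500, cutoff = 1000)
  t <- 0:1500
  v <- ifelse(t >= 600, 95, 100)
  res <- detect_withdrawal_reflectance(signal_trace(v, units = "mV"), stim)
  expect_true(res$detected)
  expect_false(res$censored)
  expect_equal(res$latency, 110)
  expect_equal(res$channel, "reflectance")
})

test_that("flat trace is censored at the cutoff with latency = censor time", {
  stim <- stimulus_event("thermal", "pulse", onset = 500, cutoff = 20000)
  tr <- signal_trace(rep(100, 20501), units = "mV")
  res <- detect_withdrawal_reflectance(tr, stim)
  expect_false(res$detected)
  expect_true(res$censored)
  expect_equal(res$latency, 20000)
  expect_equal(res$censor_time, 20000)
})

test_that("reflectance detector enforces units and trace coverage", {
  stim <- stimulus_event("optogenetic", "pulse", onset = 500, cutoff = 1000)
  expect_error(
    detect_withdrawal_reflectance(signal_trace(rep(1, 1501), units = "px"),
                                  stim),
    "must be in mV")
  expect_error(
    detect_withdrawal_reflectance(signal_trace(rep(1, 800), units = "mV"),
                                  stim),
    "cutoff")
  expect_error(
    detect_withdrawal_reflectance(
      signal_trace(rep(1, 1501), t0 = 200, units = "mV"), stim),
    "baseline")
})

test_that("sub-threshold excursions no longer than the persistence are never reported", {
  stim <- stimulus_event("optogenetic", "pulse", onset = 500, cutoff = 1000)
  for (run_ms in 1:20) {
    v <- make_excursion_trace(run_ms)
    res <- detect_withdrawal_reflectance(signal_trace(v, units = "mV"), stim)
    expect_false(res$detected, info = paste("excursion", run_ms, "ms"))
    expect_true(res$censored)
  }
  # one sample beyond the persistence bound is reported, at the crossing
  v <- make_excursion_trace(21)
  res <- detect_withdrawal_reflectance(signal_trace(v, units = "mV"), stim)
  expect_true(res$detected)
  expect_equal(res$latency, 200)
})

test_that("height detector uses the rise criterion without smoothing", {
  stim <- stimulus_event("optogenetic", "pulse", onset = 500, cutoff = 1000)
  t <- 0:1500
  up <- signal_trace(ifelse(t >= 620, 30, 20), units = "px")
  res <- detect_withdrawal_height(up, stim)
  expect_true(res$detected)
  expect_equal(res$latency, 120)
  # +5 px never crosses the 6 px criterion
  small <- signal_trace(ifelse(t >= 620, 25, 20), units = "px")
  expect_false(detect_withdrawal_height(small, stim)$detected)
  # pressing the paw down (height dip) is not a withdrawal
  dip <- signal_trace(ifelse(t >= 620, 0, 20), units = "px")
  res_dip <- detect_withdrawal_height(dip, stim)
  expect_false(res_dip$detected)
  expect_true(res_dip$censored)
  expect_error(detect_withdrawal_height(
    signal_trace(rep(1, 1501), units = "mV"), stim), "must be in px")
})

test_that("force detector finds the abrupt drop and the preceding peak", {
  ft <- simulate_force_trial(40, 10, noise_sd = 0, seed = 1, cutoff = 5000)
  res <- detect_withdrawal_force(ft$trace, ft$stim)
  expect_true(res$detected)
  expect_equal(res$latency, 4000)
  expect_equal(res$threshold_force, 40)
  expect_s3_class(res, "force_result")
})

test_that("monotone ramp with no drop is censored without a threshold", {
  ft <- simulate_force_trial(100, 10, noise_sd = 0, seed = 1, cutoff = 5000)
  expect_true(is.na(ft$truth$latency))
  res <- detect_withdrawal_force(ft$trace, ft$stim)
  expect_false(res$detected)
  expect_true(res$censored)
  expect_true(is.na(res$threshold_force))
})

test_that("noisy ramp with one true 90% drop triggers only at the true drop", {
  # bounded +/- 1 mN noise on a 10 mN/s ramp; brute-force scan of the rule
  # confirms no earlier 50% deficit, and the detector agrees with the scan
  set.seed(42)
  fs <- 1000
  cutoff <- 5000
  t <- 0:cutoff
  ramp <- pmin(10 * t / 1000, 40)
  v <- ifelse(t <= 4000, ramp, 0.1 * 40) # drop to 10% of peak (90% drop)
  v <- v + runif(length(v), -1, 1)
  tr <- signal_trace(v, fs = fs, units = "mN")
  stim <- stimulus_event("mechanical", "ramp", onset = 0, intensity = 10,
                         cutoff = cutoff)
  res <- detect_withdrawal_force(tr, stim)
  orc <- oracle_detect_force(v, fs, 0, cutoff)
  expect_true(res$detected)
  expect_equal(res$latency, orc$latency)
  expect_equal(res$threshold_force, orc$threshold)
  expect_gte(res$latency, 3990)
})

test_that("all-nonpositive force trace censors with a degenerate flag", {
  stim <- stimulus_event("mechanical", "ramp", onset = 0, cutoff = 1000)
  tr <- signal_trace(rep(-0.1, 1001), units = "mN")
  res <- detect_withdrawal_force(tr, stim)
  expect_true(res$censored)
  expect_true(is.na(res$threshold_force))
  expect_true(isTRUE(attr(res, "degenerate")))
})

test_that("noiseless detector latency stays within the smoothing bound of truth", {
  stim <- stimulus_event("optogenetic", "pulse", onset = 500, cutoff = 800)
  for (truth in c(50, 113, 150, 237, 490)) {
    paw <- virtual_paw(true_latency = truth, noise_sd = 0)
    sim <- simulate_reflectance_trial(paw, stim, seed = 1)
    res <- detect_withdrawal_reflectance(sim$trace, stim)
    expect_true(res$detected)
    expect_lte(abs(res$latency - truth), 27)
    # and matches the brute-force rule evaluation exactly
    orc <- oracle_detect_reflectance(sim$trace$values, 1000, sim$trace$t0,
                                     500, 800)
    expect_equal(res$latency, orc$latency)
  }
})

test_that("mis-detection fraction does not decrease with noise", {
  stim <- stimulus_event("optogenetic", "pulse", onset = 500, cutoff = 800)
  noise_grid <- c(0, 0.5, 1, 2, 4)
  n_trials <- 100
  frac <- vapply(seq_along(noise_grid), function(g) {
    bad <- 0
    for (i in seq_len(n_trials)) {
      paw <- virtual_paw(true_latency = 150, reflectance_drop = 5,
                         noise_sd = noise_grid[g])
      sim <- simulate_reflectance_trial(paw, stim, seed = 1000 * g + i)
      res <- detect_withdrawal_reflectance(sim$trace, stim)
      if (!res$detected || abs(res$latency - 150) > 27) bad <- bad + 1
    }
    bad / n_trials
  }, numeric(1))
  expect_true(all(diff(frac) >= 0))
})

test_that("detected and censored counts partition any batch of trials", {
  stim <- stimulus_event("optogenetic", "pulse", onset = 500, cutoff = 600)
  n <- 50
  res <- lapply(seq_len(n), function(i) {
    # half the trials withdraw after the cutoff -> censored
    truth <- if (i %% 2 == 0) 150 else 700
    paw <- virtual_paw(true_latency = truth, noise_sd = 1)
    sim <- simulate_reflectance_trial(paw, stim, seed = i)
    detect_withdrawal_reflectance(sim$trace, stim)
  })
  n_det <- sum(vapply(res, `[[`, TRUE, "detected"))
  n_cen <- sum(vapply(res, `[[`, TRUE, "censored"))
  expect_equal(n_det + n_cen, n)
})

test_that("result invariants are enforced by the constructor", {
  expect_error(withdrawal_result(TRUE, 0, FALSE, 100, "reflectance"),
               "latency")
  expect_error(withdrawal_result(TRUE, 200, TRUE, 100, "reflectance"))
  r <- withdrawal_result(FALSE, 20000, TRUE, 20000, "reflectance")
  expect_equal(r$latency, r$censor_time)
})
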