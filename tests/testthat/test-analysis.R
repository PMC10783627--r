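test_that("snr_db and coefficient_of_variation match their definitions", {
  expect_equal(snr_db(c(1.8, 2, 2.2)), 20) # mean 2, sd 0.2
  x <- c(0.9, 1, 1.1, 0.8, 1.2)
  expect_equal(snr_db(x), 10 * log10(mean(x)^2 / sd(x)^2))
  expect_equal(coefficient_of_variation(c(9, 10, 11)), 0.1)
  expect_equal(coefficient_of_variation(x), sd(x) / mean(x))
  # oracle agreement on random vectors
  set.seed(1)
  for (i in 1:20) {
    v <- rnorm(50, mean = 10, sd = runif(1, 0.5, 3))
    expect_equal(snr_db(v), 10 * log10((mean(v) / sd(v))^2))
    expect_equal(coefficient_of_variation(v), sd(v) / mean(v))
  }
  # scale invariance of CV
  expect_equal(coefficient_of_variation(3 * x), coefficient_of_variation(x))
  expect_error(snr_db(rep(1, 5)), "zero variance")
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
  expect_warning(res <- snr_db(c(-1, 0, 1)), "zero mean")
  expect_equal(res, -Inf)
})

test_that("bland_altman recovers an injected proportional bias exactly", {
  # difference = -1.45 + 0.021 * average, averages 20..160 ms
  avg <- seq(20, 160, by = 5)
  d <- -1.45 + 0.021 * avg
  ba <- bland_altman(avg + d / 2, avg - d / 2, query_avgs = c(25, 150))
  expect_equal(ba$slope, 0.021, tolerance = 1e-12)
  expect_equal(ba$intercept, -1.45, tolerance = 1e-12)
  expect_equal(ba$query$predicted_diff[1], -0.925, tolerance = 1e-9)
  expect_equal(ba$query$predicted_diff[2], 1.7, tolerance = 1e-9)
})

test_that("bland_altman recognizes fixed bias, zero bias and degeneracy", {
  m <- c(20, 45, 80, 120, 150)
  same <- bland_altman(m, m)
  expect_equal(same$mean_diff, 0)
  expect_equal(same$slope, 0)
  shift <- bland_altman(m + 5, m)
  expect_equal(shift$mean_diff, 5)
  expect_equal(shift$slope, 0, tolerance = 1e-12)
  deg <- bland_altman(c(10, 10, 10), c(10, 10, 10))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$slope))
  expect_error(bland_altman(1:2, 1:2), "at least 3")
})

test_that("bland_altman estimates are unbiased under noise and the band covers", {
  set.seed(11)
  n_rep <- 200
  slopes <- means <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    avg <- runif(60, 20, 160)
    d <- -1.45 + 0.021 * avg + rnorm(60, 0, 1)
    ba <- bland_altman(avg + d / 2, avg - d / 2)
    slopes[r] <- ba$slope
    means[r] <- ba$mean_diff
  }
  expect_lt(abs(mean(slopes) - 0.021), 0.003)
  # large-sample prediction band contains >= 90 % of points
  avg <- runif(2000, 20, 160)
  d <- -1.45 + 0.021 * avg + rnorm(2000, 0, 1)
  ba <- bland_altman(avg + d / 2, avg - d / 2)
  pred <- predict(ba$fit, newdata = data.frame(a = avg),
                  interval = "prediction")
  cover <- mean(d >= pred[, "lwr"] & d <= pred[, "upr"])
  expect_gte(cover, 0.9)
})

test_that("fast/slow classification uses a strict 75 ms boundary for fast", {
  cls <- classify_fast_slow(c(74, 76, 75))
  expect_equal(as.character(cls$labels), c("fast", "slow", "slow"))
  expect_equal(sum(cls$counts), 3)
  grouped <- classify_fast_slow(c(30, 40, 200, 220), cutoff = 75,
                                group = c("hi", "hi", "lo", "lo"))
  expect_equal(dim(grouped$counts), c(2L, 2L))
  expect_false(grouped$degenerate)
  onesided <- classify_fast_slow(c(30, 40), cutoff = 75)
  expect_true(onesided$degenerate)
  expect_error(classify_fast_slow(c(-5, 10)), "positive")
  # partition invariant
  set.seed(3)
  lat <- rlnorm(100, log(75), 0.6)
  cls2 <- classify_fast_slow(lat)
  expect_equal(sum(cls2$counts), 100)
})

test_that("chi-square of proportions is Pearson without continuity correction", {
  even <- matrix(c(10, 10, 10, 10), 2)
  expect_equal(chi2_proportions(even)$statistic, 0)
  diag <- matrix(c(20, 0, 0, 20), 2)
  res <- chi2_proportions(diag)
  expect_equal(res$statistic, 40)
  expect_equal(res$df, 1)
  expect_error(chi2_proportions(matrix(c(0, 0, 5, 5), 2,
                                       byrow = TRUE)),
               "expected count of zero")
  expect_error(chi2_proportions(matrix(1:3, 1)), "2 x 2")
})

test_that("power-law fits recover noiseless generator curves exactly", {
  x <- c(0.5, 1, 2, 5, 10, 20, 50)
  fast <- fit_power_law(x, 49.8 * x^-0.17)
  expect_equal(fast$a, 49.8, tolerance = 1e-9)
  expect_equal(fast$b, -0.17, tolerance = 1e-9)
  slow <- fit_power_law(x, 254.8 * x^-0.29)
  expect_equal(slow$a, 254.8, tolerance = 1e-9)
  expect_equal(slow$b, -0.29, tolerance = 1e-9)
  flat <- fit_power_law(x, rep(7, length(x)))
  expect_equal(flat$b, 0, tolerance = 1e-12)
  expect_equal(flat$a, 7, tolerance = 1e-12)
  expect_error(fit_power_law(c(-1, 1, 2), c(1, 2, 3)), "strictly positive")
  expect_equal(predict(fast, 10), 49.8 * 10^-0.17, tolerance = 1e-9)
})

test_that("power-law exponent is unbiased under symmetric log-normal noise", {
  set.seed(5)
  x <- rep(c(1, 2, 5, 10, 20), each = 4)
  b_hat <- vapply(1:200, function(i) {
    y <- 49.8 * x^-0.17 * exp(rnorm(length(x), 0, 0.2))
    fit_power_law(x, y)$b
  }, numeric(1))
  expect_lt(abs(mean(b_hat) - (-0.17)), 0.01)
})

test_that("psychometric threshold sits at the geometric midpoint for step data", {
  # 0 % below, 100 % above, symmetric log-spaced grid around the gap
  intens <- rep(c(1, 2, 4, 8), each = 5)
  out <- as.numeric(intens > 2.5)
  fit <- fit_psychometric(intens, out)
  expect_true(fit$separation)
  expect_equal(fit$threshold, sqrt(2 * 4), tolerance = 0.05)
  expect_error(fit_psychometric(rep(1, 10), rep(0:1, 5)),
               "2 distinct")
  und <- fit_psychometric(c(1, 2, 1, 2), c(0, 0, 0, 0))
  expect_true(is.na(und$threshold))
  expect_equal(und$flag, "undefined")
})

test_that("psychometric threshold is recovered within 10% at the 5x5 design", {
  # 5 intensities x 5 trials, logistic generator with known threshold
  truth <- 2
  intens <- rep(truth * 2^seq(-2, 2), each = 5)
  slope <- 2.5 # on log intensity
  th <- vapply(1:200, function(s) {
    set.seed(s)
    p <- plogis(slope * (log(intens) - log(truth)))
    out <- rbinom(length(p), 1, p)
    if (all(out == 0) || all(out == 1)) return(NA_real_)
    fit_psychometric(intens, out)$threshold
  }, numeric(1))
  expect_lt(abs(median(th, na.rm = TRUE) - truth) / truth, 0.1)
})

test_that("latency-distribution comparison returns KS extremes and CV contrast", {
  a <- data.frame(unit = rep(c("m1", "m2"), each = 5),
                  latency = c(rnorm(5, 100, 10), rnorm(5, 110, 10)))
  same <- compare_latency_distributions(a, a)
  expect_equal(same$ks$D, 0)
  pointA <- data.frame(unit = rep(c("m1", "m2"), each = 3), latency = 1)
  pointB <- data.frame(unit = rep(c("m3", "m4"), each = 3), latency = 2)
  # constant-per-unit latencies give CV 0; point masses give D = 1
  apart <- compare_latency_distributions(pointA, pointB)
  expect_equal(apart$ks$D, 1)
  expect_true(all(apart$cv_A == 0))
  set.seed(8)
  varied <- data.frame(unit = rep(c("m5", "m6", "m7"), each = 7),
                       latency = rlnorm(21, log(5), 0.5))
  mixed <- compare_latency_distributions(pointA, varied)
  expect_lt(mixed$cv_test$t, 0) # group A (all-zero CVs) below group B
  # unit with < 2 trials is excluded with a warning
  a_bad <- rbind(a, data.frame(unit = "m9", latency = 50))
  expect_warning(res <- compare_latency_distributions(a_bad, varied),
                 "m9")
  expect_false("m9" %in% names(res$cv_A))
})

test_that("behavior-latency association finds exact linear relations", {
  set.seed(2)
  lat <- runif(30, 1, 20)
  res <- behavior_latency_association(lat, 2 * lat, mode = "linear",
                                      boot_reps = 200, seed = 4)
  expect_equal(res$slope, 2, tolerance = 1e-9)
  expect_lt(res$p, 1e-10)
  expect_true(res$ci[1] <= 2 && 2 <= res$ci[2])
  # fixed seed -> identical bootstrap CI
  res2 <- behavior_latency_association(lat, 2 * lat, mode = "linear",
                                       boot_reps = 200, seed = 4)
  expect_identical(res$ci, res2$ci)
})

test_that("logistic association detects a latency-dependent behavior", {
  set.seed(9)
  lat <- runif(60, 1, 20)
  flag <- rbinom(60, 1, plogis(3 - 0.4 * lat)) # guarding after short latency
  if (length(unique(flag)) == 2) {
    res <- behavior_latency_association(lat, flag, mode = "logistic",
                                        boot_reps = 200, seed = 1)
    expect_lt(res$slope, 0)
    if (res$separation) {
      # model-based p unreliable; the bootstrap CI carries the inference
      expect_true(is.na(res$p))
      expect_lt(res$ci[2], 0)
    } else {
      expect_lt(res$p, 0.05)
    }
  }
  expect_error(behavior_latency_association(lat[1:5], flag[1:5]),
               "at least 10")
  expect_error(behavior_latency_association(lat, rep(1, 60),
                                            mode = "logistic"),
               "both outcome classes")
})

test_that("permuted behavior labels give a controlled false-positive rate", {
  set.seed(12)
  lat <- rlnorm(30, log(8), 0.5)
  flag <- rep(c(0, 1), c(18, 12))
  pvals <- vapply(1:200, function(s) {
    perm <- with_seed <- NULL # guard against accidental capture
    set.seed(s + 5000)
    f <- sample(flag)
    r <- behavior_latency_association(lat, f, mode = "logistic",
                                      boot_reps = 0)
    r$p
  }, numeric(1))
  pvals <- pvals[!is.na(pvals)]
  expect_lte(mean(pvals < 0.05), 0.10)
})

test_that("a simulated intensity shift is detected by classification + chi-square", {
  # two-condition experiment: high intensity shifts latencies fast
  detect_p <- vapply(1:50, function(s) {
    set.seed(s)
    low <- rlnorm(30, log(150), 0.35) # mostly slow
    high <- rlnorm(30, log(40), 0.35) # mostly fast
    cls <- classify_fast_slow(c(low, high),
                              group = rep(c("low", "high"), each = 30))
    if (any(colSums(cls$counts) == 0)) return(NA_real_)
    chi2_proportions(cls$counts)$p
  }, numeric(1))
  expect_gt(mean(detect_p < 0.05, na.rm = TRUE), 0.9)
})
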