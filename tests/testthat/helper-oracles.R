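# Independent brute-force oracles: naive sample-by-sample evaluation of the
# detection rules, deliberately written without reusing the package's
# vectorized implementations.

oracle_smooth <- function(values, n) {
  vapply(seq_along(values), function(k) {
    mean(values[max(1, k - n + 1):k])
  }, numeric(1))
}

# Full reflectance rule, evaluated sample by sample with explicit loops.
oracle_detect_reflectance <- function(values, fs, t0, onset, cutoff,
                                      baseline_window = 500,
                                      smooth_window = 27, drop = 2,
                                      persistence = 20) {
  dt <- 1000 / fs
  n <- max(1, round(smooth_window * fs / 1000))
  sm <- oracle_smooth(values, n)
  t <- t0 + (seq_along(values) - 1) * dt
  base <- mean(sm[t >= onset - baseline_window & t < onset])
  thr <- base - drop
  post <- which(t > onset & t <= onset + cutoff)
  run <- 0
  run_start <- NA
  for (i in post) {
    if (sm[i] < thr) {
      if (run == 0) run_start <- t[i]
      run <- run + 1
      if (run * dt > persistence) {
        return(list(detected = TRUE, latency = run_start - onset,
                    censored = FALSE))
      }
    } else {
      run <- 0
    }
  }
  list(detected = FALSE, latency = cutoff, censored = TRUE)
}

# Brute-force scan of the mechanical drop rule.
oracle_detect_force <- function(values, fs, onset, cutoff, frac = 0.5,
                                window = 50, min_peak = 5) {
  dt <- 1000 / fs
  t <- (seq_along(values) - 1) * dt
  post <- which(t > onset & t <= onset + cutoff)
  peak <- -Inf
  peak_t <- NA
  for (i in post) {
    if (values[i] > peak) {
      peak <- values[i]
      peak_t <- t[i]
    }
    if (peak > min_peak && (t[i] - peak_t) <= window &&
        values[i] < frac * peak) {
      return(list(detected = TRUE, latency = peak_t - onset,
                  threshold = peak))
    }
  }
  list(detected = FALSE, latency = cutoff, threshold = NA_real_)
}

# Trace whose SMOOTHED signal sits below threshold for exactly `run_ms` ms:
# baseline 100 mV, then a sustained deep step at `drop_at`; the trace is cut
# so only `run_ms` of sub-threshold smoothed samples exist before recovery.
make_excursion_trace <- function(run_ms, onset = 500, cutoff = 1000,
                                 fs = 1000) {
  n_total <- round((onset + cutoff) * fs / 1000) + 1
  v <- rep(100, n_total)
  t <- (seq_len(n_total) - 1) * 1000 / fs
  # deep drop whose smoothed crossing is immediate (one sample after start)
  drop_at <- onset + 200
  # drop for exactly run_ms, then jump far above baseline so the smoothed
  # signal recovers in a single sample
  v[t >= drop_at & t < drop_at + run_ms] <- 0
  v[t >= drop_at + run_ms] <- 3000
  v
}

make_noisy_trial <- function(seed, true_latency = 150, noise_sd = 1,
                             drift = 0, cutoff = 800, onset = 500) {
  stim <- stimulus_event("optogenetic", "pulse", onset = onset,
                         cutoff = cutoff)
  paw <- virtual_paw(true_latency = true_latency, noise_sd = noise_sd,
                     drift = drift)
  simulate_reflectance_trial(paw, stim, seed = seed)
}

expect_same_result <- function(a, b) {
  expect_equal(a$detected, b$detected)
  expect_equal(a$latency, b$latency)
  expect_equal(a$censored, b$censored)
}
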