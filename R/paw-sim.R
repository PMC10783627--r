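#' Virtual paw: ground-truth withdrawal kinematics
#'
#' Parameters of the simulated paw used to generate reflectance and height
#' traces with a known withdrawal time. The reflectance channel sits at
#' `reflectance_baseline` mV, drifts linearly, carries Gaussian sample noise,
#' and at `true_latency` ms after stimulus onset drops by `reflectance_drop`
#' mV over `transition_ms` (a linear transient). The paw-height channel rises
#' at `withdrawal_speed` px/ms from the same moment.
#'
#' @param true_latency Ground-truth withdrawal latency in ms (> 0).
#' @param withdrawal_speed Paw lift speed in px/ms (default 1).
#' @param reflectance_baseline Baseline reflectance in mV (default 100).
#' @param reflectance_drop Reflectance drop at withdrawal in mV (default 5).
#' @param noise_sd Gaussian noise SD in mV (default 0).
#' @param drift Baseline drift in mV/s (default 0).
#' @param transition_ms Duration of the linear reflectance transient in ms
#'   (default 10).
#' @param height_baseline Resting paw height in px (default 20).
#' @param height_rise Total paw lift in px (default 40).
#' @return An object of class `virtual_paw`.
#' @export
virtual_paw <- function(true_latency = 150, withdrawal_speed = 1,
                        reflectance_baseline = 100, reflectance_drop = 5,
                        noise_sd = 0, drift = 0, transition_ms = 10,
                        height_baseline = 20, height_rise = 40) {
  if (true_latency <= 0) stop("true_latency must be > 0")
  if (reflectance_drop <= 0) stop("reflectance_drop must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(true_latency = true_latency,
                 withdrawal_speed = withdrawal_speed,
                 reflectance_baseline = reflectance_baseline,
                 reflectance_drop = reflectance_drop,
                 noise_sd = noise_sd, drift = drift,
                 transition_ms = transition_ms,
                 height_baseline = height_baseline,
                 height_rise = height_rise),
            class = "virtual_paw")
}

#' Simulate a reflectance trial with known ground truth
#'
#' Generates the red-reflectance trace for one trial: baseline + linear
#' drift + Gaussian noise, with the withdrawal transient (linear drop of
#' `reflectance_drop` mV over `transition_ms`) starting exactly at
#' `stim$onset + paw$true_latency`. If that moment lies beyond the trace no
#' transient occurs and the detector will censor the trial.
#'
#' @param paw A [virtual_paw()].
#' @param stim A [stimulus_event()]; the trace spans
#'   `[onset - baseline_pad, onset + cutoff]`.
#' @param fs Sampling rate in Hz (default 1000).
#' @param seed Integer seed (determinism contract: same seed, same trace).
#' @param baseline_pad Pre-onset coverage in ms (default 500).
#' @return A list with elements `trace` ([signal_trace()] in mV), `truth`
#'   (the ground-truth latency in ms) and `stim`.
#' @export
simulate_reflectance_trial <- function(paw, stim, fs = 1000, seed = 1,
                                       baseline_pad = 500) {
  stopifnot(inherits(paw, "virtual_paw"), inherits(stim, "stimulus_event"))
  t0 <- stim$onset - baseline_pad
  n <- as.integer(round((baseline_pad + stim$cutoff) * fs / 1000)) + 1L
  t <- t0 + (seq_len(n) - 1) * 1000 / fs
  drop_t <- stim$onset + paw$true_latency
  frac <- pmin(1, pmax(0, (t - drop_t) / paw$transition_ms))
  if (paw$transition_ms <= 0) frac <- as.numeric(t >= drop_t)
  vals <- paw$reflectance_baseline + paw$drift * (t - t0) / 1000 -
    paw$reflectance_drop * frac
  vals <- vals + with_seed(seed, stats::rnorm(n, 0, paw$noise_sd))
  list(trace = signal_trace(vals, fs = fs, t0 = t0, units = "mV"),
       truth = paw$true_latency, stim = stim)
}

#' Simulate a paw-height trial with known ground truth
#'
#' Companion generator to [simulate_reflectance_trial()] for the high-speed
#' video channel: paw height holds at `height_baseline`, then rises at
#' `withdrawal_speed` px/ms (up to `height_rise` px) from
#' `stim$onset + paw$true_latency`.
#'
#' @inheritParams simulate_reflectance_trial
#' @param noise_sd Per-frame height noise SD in px (default `paw$noise_sd`).
#' @return A list with `trace` ([signal_trace()] in px), `truth` and `stim`.
#' @export
simulate_height_trial <- function(paw, stim, fs = 1000, seed = 1,
                                  baseline_pad = 500, noise_sd = 0) {
  stopifnot(inherits(paw, "virtual_paw"), inherits(stim, "stimulus_event"))
  t0 <- stim$onset - baseline_pad
  n <- as.integer(round((baseline_pad + stim$cutoff) * fs / 1000)) + 1L
  t <- t0 + (seq_len(n) - 1) * 1000 / fs
  drop_t <- stim$onset + paw$true_latency
  rise <- pmin(paw$height_rise,
               pmax(0, (t - drop_t) * paw$withdrawal_speed))
  vals <- paw$height_baseline + rise +
    with_seed(seed, stats::rnorm(n, 0, noise_sd))
  list(trace = signal_trace(vals, fs = fs, t0 = t0, units = "px"),
       truth = paw$true_latency, stim = stim)
}

#' Simulate a mechanical (indenter) trial with known ground truth
#'
#' The commanded force ramps at `ramp_rate` mN/s from stimulus onset until
#' it reaches `withdrawal_force`, at which point the paw withdraws and the
#' measured force collapses to ~0 within `collapse_ms` (default 5 ms);
#' thereafter the sensor reads noise around zero until the cutoff. If the
#' ramp would only reach `withdrawal_force` after the cutoff, no withdrawal
#' occurs and the ramp runs to the cutoff (a censored trial).
#'
#' @param withdrawal_force Ground-truth threshold force in mN.
#' @param ramp_rate Ramp rate in mN/s (> 0).
#' @param noise_sd Gaussian force-sensor noise SD in mN (default 0.2).
#' @param fs Sampling rate in Hz (default 1000).
#' @param seed Integer seed.
#' @param cutoff Stimulus cutoff in ms (default 20000).
#' @param collapse_ms Duration of the post-withdrawal force collapse
#'   (default 5).
#' @return A list with `trace` ([signal_trace()] in mN), `truth` (list with
#'   `latency` ms and `threshold` mN, both `NA` when censored) and `stim`
#'   (a mechanical ramp [stimulus_event()] with onset 0).
#' @export
simulate_force_trial <- function(withdrawal_force, ramp_rate, noise_sd = 0.2,
                                 fs = 1000, seed = 1, cutoff = 20000,
                                 collapse_ms = 5) {
  if (ramp_rate <= 0) stop("ramp_rate must be > 0")
  stim <- stimulus_event("mechanical", "ramp", onset = 0,
                         intensity = ramp_rate, cutoff = cutoff)
  n <- as.integer(round(cutoff * fs / 1000)) + 1L
  t <- (seq_len(n) - 1) * 1000 / fs
  lat <- withdrawal_force / ramp_rate * 1000
  ramp <- ramp_rate * t / 1000
  if (lat < cutoff) {
    pre <- t <= lat
    coll <- t > lat & t <= lat + collapse_ms
    vals <- ifelse(pre, ramp,
                   ifelse(coll,
                          withdrawal_force * (1 - (t - lat) / collapse_ms),
                          0))
    truth <- list(latency = lat, threshold = withdrawal_force)
  } else {
    vals <- ramp
    truth <- list(latency = NA_real_, threshold = NA_real_)
  }
  vals <- vals + with_seed(seed, stats::rnorm(n, 0, noise_sd))
  list(trace = signal_trace(vals, fs = fs, t0 = 0, units = "mN"),
       truth = truth, stim = stim)
}

#' Simulate a pose key-point stream
#'
#' Emits per-frame key points (snout, fore paws, hind paws, tail base) with
#' per-frame Gaussian coordinate noise, emulating live pose estimation on
#' 640x480 substage video. The default noise SD, 3.33 px, matches the
#' pose-network test error for the target hind paw. Two motion models:
#' `"stationary_bouts"` alternates stationary epochs with instantaneous
#' relocations of the animal; `"random_walk"` moves the body every frame.
#' Coordinates use the image convention (origin top-left, y down).
#'
#' @param motion `"stationary_bouts"` (default) or `"random_walk"`.
#' @param bout_params List of motion parameters: `bout_ms` (mean stationary
#'   bout length, default 4000), `jump_px` (relocation scale, default 80),
#'   `step_px` (random-walk per-frame step SD, default 2), `confidence`
#'   (reported key-point confidence, default 0.95), `start` (initial target
#'   paw position, default arena center).
#' @param fps Frames per second (default 30).
#' @param duration Stream duration in ms.
#' @param noise_px Per-frame coordinate noise SD in px (default 3.33).
#' @param seed Integer seed.
#' @param arena Arena (frame) size in px, `c(width, height)`
#'   (default 640x480).
#' @return A data.frame of class `keypoint_stream` in long format with
#'   columns `frame`, `time_ms`, `part`, `x_px`, `y_px`, `confidence`, and
#'   attributes `fps` and `arena`.
#' @export
simulate_keypoints <- function(motion = c("stationary_bouts", "random_walk"),
                               bout_params = list(), fps = 30,
                               duration = 10000, noise_px = 3.33, seed = 1,
                               arena = c(640, 480)) {
  motion <- match.arg(motion)
  if (duration <= 0) stop("duration must be > 0")
  if (fps <= 0) stop("fps must be > 0")
  bp <- utils::modifyList(
    list(bout_ms = 4000, jump_px = 80, step_px = 2, confidence = 0.95,
         start = arena / 2),
    bout_params)
  n <- max(1L, as.integer(floor(duration * fps / 1000)))
  parts <- c("snout", "paw_front_left", "paw_front_right",
             "paw_hind_left", "paw_hind_right", "tail_base")
  # body-frame offsets of each part around the target hind paw (px)
  offs <- rbind(snout = c(60, -40), paw_front_left = c(40, -20),
                paw_front_right = c(55, 0), paw_hind_left = c(0, 0),
                paw_hind_right = c(15, 25), tail_base = c(-45, 10))
  with_seed(seed, {
    if (motion == "stationary_bouts") {
      frames_per_bout <- max(1L, as.integer(round(bp$bout_ms * fps / 1000)))
      n_bouts <- ceiling(n / frames_per_bout)
      cx <- numeric(0); cy <- numeric(0)
      px <- bp$start[1]; py <- bp$start[2]
      for (b in seq_len(n_bouts)) {
        cx <- c(cx, rep(px, frames_per_bout))
        cy <- c(cy, rep(py, frames_per_bout))
        px <- min(max(px + stats::rnorm(1, 0, bp$jump_px), 40), arena[1] - 40)
        py <- min(max(py + stats::rnorm(1, 0, bp$jump_px), 40), arena[2] - 40)
      }
      cx <- cx[seq_len(n)]; cy <- cy[seq_len(n)]
    } else {
      cx <- bp$start[1] + cumsum(stats::rnorm(n, 0, bp$step_px))
      cy <- bp$start[2] + cumsum(stats::rnorm(n, 0, bp$step_px))
      cx <- pmin(pmax(cx, 0), arena[1]); cy <- pmin(pmax(cy, 0), arena[2])
    }
    out <- do.call(rbind, lapply(seq_along(parts), function(i) {
      data.frame(frame = seq_len(n) - 1L,
                 time_ms = (seq_len(n) - 1) * 1000 / fps,
                 part = parts[i],
                 x_px = cx + offs[i, 1] + stats::rnorm(n, 0, noise_px),
                 y_px = cy + offs[i, 2] + stats::rnorm(n, 0, noise_px),
                 confidence = bp$confidence,
                 stringsAsFactors = FALSE)
    }))
    out <- out[order(out$frame, match(out$part, parts)), ]
    rownames(out) <- NULL
    structure(out, fps = fps, arena = arena,
              class = c("keypoint_stream", "data.frame"))
  })
}

#' Virtual rig: everything needed to run one animal's trials in silico
#'
#' Bundles a [virtual_paw()], the key-point motion parameters, and the seeds
#' that make every generated trial reproducible.
#'
#' @param mouse_id Animal identifier.
#' @param paw A [virtual_paw()].
#' @param motion Key-point motion model (see [simulate_keypoints()]).
#' @param bout_params Motion parameters (see [simulate_keypoints()]).
#' @param noise_px Key-point noise SD in px.
#' @param fps Video frame rate.
#' @param arena Frame size in px.
#' @param seed Master seed for this rig's generators.
#' @return An object of class `virtual_rig`.
#' @export
virtual_rig <- function(mouse_id = "m1", paw = virtual_paw(),
                        motion = "stationary_bouts", bout_params = list(),
                        noise_px = 3.33, fps = 30, arena = c(640, 480),
                        seed = 1) {
  stopifnot(inherits(paw, "virtual_paw"))
  structure(list(mouse_id = mouse_id, paw = paw, motion = motion,
                 bout_params = bout_params, noise_px = noise_px, fps = fps,
                 arena = arena, seed = seed),
            class = "virtual_rig")
}
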