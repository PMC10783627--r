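#' Aiming-controller configuration
#'
#' Parameters of the automated-aiming loop: the stimulator is translated
#' with a velocity proportional to the pixel error between the target paw
#' and the crosshairs (clamped at `max_speed`), no motion command is issued
#' inside the `deadband`, and stimulation fires only after the target has
#' stayed inside the deadband for an uninterrupted `settle_period`. A
#' separate give-up timer abandons animals that never settle.
#'
#' @param gain Proportional gain (commanded px/step per px of error),
#'   in (0, 1] for monotone, overshoot-free convergence (default 0.5).
#' @param max_speed Velocity clamp in px/step (default 50).
#' @param deadband Aiming tolerance in px (default 3).
#' @param settle_period Required uninterrupted in-deadband time in ms
#'   before stimulating (default 2000).
#' @param giveup_period Total time before skipping the animal, ms
#'   (default 30000).
#' @param frame_interval Control-loop period in ms (default 33, one frame
#'   of standard 30 fps video).
#' @param deadband_metric `"max"` (default; per-axis `|dx|`,`|dy|` both
#'   within tolerance) or `"euclidean"`.
#' @param min_confidence Key points below this confidence are treated as
#'   target-lost: the actuator holds and the settle timer resets
#'   (default 0.5).
#' @param error_filter_frames Width (frames) of the trailing average applied
#'   to the tracked target position before computing the error (default 15,
#'   i.e. 0.5 s at 30 fps); 1 disables filtering. Per-frame pose estimates
#'   carry a few px of noise, comparable to the 3 px tolerance, so the raw
#'   per-frame error would chatter in and out of the deadband.
#' @return An object of class `controller_config`.
#' @export
controller_config <- function(gain = 0.5, max_speed = 50, deadband = 3,
                              settle_period = 2000, giveup_period = 30000,
                              frame_interval = 33,
                              deadband_metric = c("max", "euclidean"),
                              min_confidence = 0.5,
                              error_filter_frames = 15) {
  deadband_metric <- match.arg(deadband_metric)
  if (gain <= 0) stop("gain must be > 0")
  if (deadband <= 0) stop("deadband must be > 0")
  if (settle_period <= 0) stop("settle_period must be > 0")
  if (max_speed <= 0) stop("max_speed must be > 0")
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  if (error_filter_frames < 1) stop("error_filter_frames must be >= 1")
  structure(list(gain = gain, max_speed = max_speed, deadband = deadband,
                 settle_period = settle_period, giveup_period = giveup_period,
                 frame_interval = frame_interval,
                 deadband_metric = deadband_metric,
                 min_confidence = min_confidence,
                 error_filter_frames = error_filter_frames),
            class = "controller_config")
}

#' Pixel error between target and crosshairs
#'
#' Image-convention (y down) deviation of the tracked target from the
#' stimulation crosshairs.
#'
#' @param target Target coordinates `c(x, y)` in px.
#' @param crosshair Crosshair coordinates `c(x, y)` in px (default the
#'   center of a 640x480 frame).
#' @return Numeric `c(dx, dy)`.
#' @export
pixel_error <- function(target, crosshair = c(320, 240)) {
  if (!all(is.finite(target)) || !all(is.finite(crosshair))) {
    stop("coordinates must be finite")
  }
  c(dx = target[[1]] - crosshair[[1]], dy = target[[2]] - crosshair[[2]])
}

error_in_deadband <- function(error, cfg) {
  if (cfg$deadband_metric == "euclidean") {
    sqrt(sum(error^2)) <= cfg$deadband
  } else {
    max(abs(error)) <= cfg$deadband
  }
}

#' Initial aiming state
#'
#' @param error Initial pixel error `c(dx, dy)`.
#' @return An object of class `aiming_state` with phase `"AIMING"`.
#' @export
aiming_state <- function(error = c(0, 0)) {
  structure(list(phase = "AIMING", error = error, settle_elapsed = 0,
                 total_elapsed = 0),
            class = "aiming_state")
}

#' One step of the proportional aiming controller
#'
#' Inside the deadband the controller issues no motion and accrues settle
#' time; outside it commands a velocity proportional to the error (clamped
#' per axis at `max_speed`), directed to reduce the error, and resets the
#' settle timer. Total elapsed time always advances by one frame interval.
#'
#' @param state An [aiming_state()].
#' @param error Current pixel error `c(dx, dy)`.
#' @param cfg A [controller_config()].
#' @return A list with the updated `state` and the commanded `velocity`
#'   `c(vx, vy)` in px/step.
#' @export
controller_step <- function(state, error, cfg = controller_config()) {
  stopifnot(inherits(state, "aiming_state"), inherits(cfg, "controller_config"))
  state$error <- error
  state$total_elapsed <- state$total_elapsed + cfg$frame_interval
  if (error_in_deadband(error, cfg)) {
    state$phase <- "SETTLING"
    state$settle_elapsed <- state$settle_elapsed + cfg$frame_interval
    velocity <- c(vx = 0, vy = 0)
  } else {
    state$phase <- "AIMING"
    state$settle_elapsed <- 0
    v <- cfg$gain * error
    v <- pmin(pmax(v, -cfg$max_speed), cfg$max_speed)
    velocity <- c(vx = unname(v[1]), vy = unname(v[2]))
  }
  list(state = state, velocity = velocity)
}

#' Run the aiming loop over a key-point stream
#'
#' Replays a [simulate_keypoints()] stream through the proportional
#' controller against an ideal velocity-follower actuator: each frame the
#' tracked target position (trailing-averaged over
#' `cfg$error_filter_frames` frames) is compared with the current aim
#' point; the commanded velocity moves the aim point before the next frame.
#' The loop ends with `"STIMULATE"` once the settle timer reaches
#' `settle_period`, or `"SKIPPED"` once `giveup_period` elapses first.
#'
#' @param stream A `keypoint_stream` (see [simulate_keypoints()]).
#' @param cfg A [controller_config()].
#' @param target_part Which key point to aim at (default
#'   `"paw_hind_left"`).
#' @param crosshair Crosshair position in px; default the frame center.
#' @return A list of class `aiming_run`: `outcome` (`"STIMULATE"` or
#'   `"SKIPPED"`), `stim_time` (ms from stream start; `NA` if skipped),
#'   and `history`, a data.frame with one row per processed frame
#'   (`frame`, `time_ms`, `phase`, `ex`, `ey`, `vx`, `vy`,
#'   `settle_elapsed`).
#' @export
run_aiming <- function(stream, cfg = controller_config(),
                       target_part = "paw_hind_left", crosshair = NULL) {
  stopifnot(inherits(stream, "keypoint_stream"))
  kp <- stream[stream$part == target_part, , drop = FALSE]
  if (nrow(kp) == 0L) stop("empty key-point stream for target part")
  if (is.null(crosshair)) crosshair <- attr(stream, "arena") / 2
  fps <- attr(stream, "fps")
  dt <- 1000 / fps
  aim <- c(crosshair[[1]], crosshair[[2]]) # current aim point (arena coords)
  k <- cfg$error_filter_frames
  bufx <- rep(NA_real_, k); bufy <- rep(NA_real_, k)
  state <- aiming_state()
  n <- nrow(kp)
  hist <- data.frame(frame = kp$frame, time_ms = kp$time_ms,
                     phase = character(n), ex = NA_real_, ey = NA_real_,
                     vx = 0, vy = 0, settle_elapsed = NA_real_,
                     stringsAsFactors = FALSE)
  outcome <- "SKIPPED"
  stim_time <- NA_real_
  last <- 0L
  for (i in seq_len(n)) {
    last <- i
    lost <- kp$confidence[i] < cfg$min_confidence
    if (!lost) {
      bufx <- c(bufx[-1], kp$x_px[i])
      bufy <- c(bufy[-1], kp$y_px[i])
    }
    have <- !is.na(bufx)
    if (lost || !any(have)) {
      # target lost: hold position, settle resets, clock advances
      state$phase <- "AIMING"
      state$settle_elapsed <- 0
      state$total_elapsed <- state$total_elapsed + dt
      hist$phase[i] <- "LOST"
      hist$settle_elapsed[i] <- 0
    } else {
      est <- c(mean(bufx[have]), mean(bufy[have]))
      err <- pixel_error(est, aim)
      cfg_dt <- cfg; cfg_dt$frame_interval <- dt
      res <- controller_step(state, err, cfg_dt)
      state <- res$state
      aim <- aim + res$velocity
      hist$phase[i] <- state$phase
      hist$ex[i] <- err[[1]]; hist$ey[i] <- err[[2]]
      hist$vx[i] <- res$velocity[[1]]; hist$vy[i] <- res$velocity[[2]]
      hist$settle_elapsed[i] <- state$settle_elapsed
    }
    if (state$settle_elapsed >= cfg$settle_period - 1e-6) {
      outcome <- "STIMULATE"
      stim_time <- kp$time_ms[i] + dt
      break
    }
    if (state$total_elapsed >= cfg$giveup_period - 1e-6) {
      outcome <- "SKIPPED"
      break
    }
  }
  structure(list(outcome = outcome, stim_time = stim_time,
                 history = hist[seq_len(last), , drop = FALSE],
                 frames = last),
            class = "aiming_run")
}
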