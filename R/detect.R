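#' Withdrawal-detection result
#'
#' Constructor for the result of a single-trial withdrawal detection.
#' Censored trials (no detection before the stimulus cutoff) report
#' `latency = censor_time` with `censored = TRUE`, never a missing value, so
#' downstream tables stay rectangular.
#'
#' @param detected Logical: was a withdrawal detected before cutoff?
#' @param latency Latency from stimulus onset in ms.
#' @param censored Logical censoring flag.
#' @param censor_time Cutoff time (ms from onset) applied to this trial.
#' @param channel Which signal the detection used: `"reflectance"`,
#'   `"height"` or `"force"`.
#' @param threshold_force Peak force (mN) preceding withdrawal; mechanical
#'   channel only.
#' @return An object of class `withdrawal_result` (with additional class
#'   `force_result` when `threshold_force` is given).
#' @export
withdrawal_result <- function(detected, latency, censored, censor_time,
                              channel = c("reflectance", "height", "force"),
                              threshold_force = NULL) {
  channel <- match.arg(channel)
  if (detected && !(latency > 0 && latency <= censor_time)) {
    stop("detected result requires 0 < latency <= censor_time")
  }
  if (censored && detected) stop("a trial cannot be both detected and censored")
  out <- list(detected = detected, latency = latency, censored = censored,
              censor_time = censor_time, channel = channel)
  cls <- "withdrawal_result"
  if (!is.null(threshold_force) || channel == "force") {
    out$threshold_force <- if (is.null(threshold_force)) NA_real_ else threshold_force
    cls <- c("force_result", cls)
  }
  structure(out, class = cls)
}

#' @export
print.withdrawal_result <- function(x, ...) {
  if (x$detected) {
    cat(sprintf("<withdrawal_result> detected, latency %.3f ms (%s)\n",
                x$latency, x$channel))
  } else if (x$censored) {
    cat(sprintf("<withdrawal_result> censored at %.0f ms (%s)\n",
                x$censor_time, x$channel))
  } else {
    cat(sprintf("<withdrawal_result> not detected (%s)\n", x$channel))
  }
  if (!is.null(x$threshold_force) && !is.na(x$threshold_force)) {
    cat(sprintf("  threshold force %.2f mN\n", x$threshold_force))
  }
  invisible(x)
}

# shared coverage check: trace must span [onset - pre, onset + post]
check_coverage <- function(trace, onset, pre, post) {
  dt <- 1000 / trace$fs
  eps <- dt / 2
  t_end <- trace$t0 + (length(trace$values) - 1) * dt
  if (trace$t0 > onset - pre + eps) stop("trace does not cover baseline window")
  if (t_end + eps < onset + post) stop("trace does not cover stimulus cutoff")
  invisible(TRUE)
}

# first qualifying sub/supra-threshold run among post-onset samples.
# `below`: logical vector over the post-onset window; a run of n samples
# qualifies iff n * dt > persistence_ms (strict).
first_qualifying_run <- function(below, dt, persistence_ms) {
  if (!any(below)) return(NA_integer_)
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$values & (r$lengths * dt > persistence_ms)
  if (!any(ok)) return(NA_integer_)
  starts[which(ok)[1L]]
}

#' Reflectance-based withdrawal detection
#'
#' Implements the rig's latency rule on the red-reflectance channel: the
#' trace is smoothed with a trailing running average
#' ([smooth_running_average()]), the baseline is the mean of the smoothed
#' signal over the `baseline_window` ms preceding stimulus onset, and a
#' withdrawal is the first post-onset sample at which the smoothed signal
#' falls strictly below `baseline - reflectance_drop` and stays below for
#' strictly longer than `persistence` ms. Latency is measured from onset to
#' the start of that sub-threshold run. If no qualifying run starts within
#' the stimulus cutoff the trial is censored at the cutoff.
#'
#' @param trace Reflectance [signal_trace()] in mV covering
#'   `[onset - baseline_window, onset + cutoff]`.
#' @param stim A [stimulus_event()].
#' @param cfg A [detection_config()].
#' @return A [withdrawal_result()] on the `"reflectance"` channel.
#' @export
detect_withdrawal_reflectance <- function(trace, stim, cfg = detection_config()) {
  stopifnot(inherits(trace, "signal_trace"), inherits(stim, "stimulus_event"),
            inherits(cfg, "detection_config"))
  if (trace$units != "mV") stop("reflectance trace must be in mV, got ", trace$units)
  check_coverage(trace, stim$onset, cfg$baseline_window, stim$cutoff)
  sm <- smooth_running_average(trace, cfg$smooth_window)
  base <- baseline_level(sm, stim$onset, cfg$baseline_window)
  thr <- base - cfg$reflectance_drop
  dt <- 1000 / trace$fs
  eps <- dt * 1e-6
  t <- trace_times(trace)
  post <- which(t > stim$onset + eps & t <= stim$onset + stim$cutoff + eps)
  below <- sm$values[post] < thr
  i <- first_qualifying_run(below, dt, cfg$persistence)
  if (is.na(i)) {
    withdrawal_result(FALSE, stim$cutoff, TRUE, stim$cutoff, "reflectance")
  } else {
    withdrawal_result(TRUE, t[post[i]] - stim$onset, FALSE, stim$cutoff,
                      "reflectance")
  }
}

#' Paw-height-based withdrawal detection
#'
#' Latency is the time from stimulus onset until paw height rises strictly
#' more than `height_rise` px above the pre-stimulus baseline (mean height
#' over the `baseline_window` ms before onset). No smoothing is applied by
#' default; set `height_smooth_window` in the config to smooth first.
#'
#' @param traj Paw-height [signal_trace()] in px.
#' @param stim A [stimulus_event()].
#' @param cfg A [detection_config()].
#' @return A [withdrawal_result()] on the `"height"` channel.
#' @export
detect_withdrawal_height <- function(traj, stim, cfg = detection_config()) {
  stopifnot(inherits(traj, "signal_trace"), inherits(stim, "stimulus_event"),
            inherits(cfg, "detection_config"))
  if (traj$units != "px") stop("height trace must be in px, got ", traj$units)
  check_coverage(traj, stim$onset, cfg$baseline_window, stim$cutoff)
  sig <- traj
  if (!is.null(cfg$height_smooth_window)) {
    sig <- smooth_running_average(traj, cfg$height_smooth_window)
  }
  base <- baseline_level(sig, stim$onset, cfg$baseline_window)
  dt <- 1000 / traj$fs
  eps <- dt * 1e-6
  t <- trace_times(traj)
  post <- which(t > stim$onset + eps & t <= stim$onset + stim$cutoff + eps)
  hit <- which(sig$values[post] > base + cfg$height_rise)
  if (length(hit) == 0L) {
    withdrawal_result(FALSE, stim$cutoff, TRUE, stim$cutoff, "height")
  } else {
    withdrawal_result(TRUE, t[post[hit[1L]]] - stim$onset, FALSE, stim$cutoff,
                      "height")
  }
}

#' Force-based withdrawal detection and mechanical threshold
#'
#' During a rising indenter ramp, withdrawal appears as an abrupt drop in
#' the measured force. The detector maintains the post-onset running peak
#' and reports a withdrawal at the first sample whose force falls strictly
#' below `force_drop_fraction` of the running peak, provided that peak was
#' attained no more than `force_drop_window` ms earlier (abruptness) and
#' exceeds `force_min_peak` mN (arming). The mechanical threshold is the
#' running peak at detection, and latency is reported at the time of that
#' peak sample, i.e. the start of the drop.
#'
#' @param force Force [signal_trace()] in mN covering `[onset, onset + cutoff]`.
#' @param stim A [stimulus_event()] (a rising mechanical ramp).
#' @param cfg A [detection_config()].
#' @return A [withdrawal_result()] of class `force_result` carrying
#'   `threshold_force` (NA when censored). If the trace never rises above
#'   zero the censored result carries attribute `degenerate = TRUE`.
#' @export
detect_withdrawal_force <- function(force, stim, cfg = detection_config()) {
  stopifnot(inherits(force, "signal_trace"), inherits(stim, "stimulus_event"),
            inherits(cfg, "detection_config"))
  if (force$units != "mN") stop("force trace must be in mN, got ", force$units)
  check_coverage(force, stim$onset, 0, stim$cutoff)
  dt <- 1000 / force$fs
  eps <- dt * 1e-6
  t <- trace_times(force)
  post <- which(t > stim$onset + eps & t <= stim$onset + stim$cutoff + eps)
  v <- force$values[post]
  if (all(v <= 0)) {
    res <- withdrawal_result(FALSE, stim$cutoff, TRUE, stim$cutoff, "force",
                             threshold_force = NA_real_)
    attr(res, "degenerate") <- TRUE
    return(res)
  }
  peak <- cummax(v)
  # index (within post) of the sample where the current running peak was set
  new_peak <- v > c(-Inf, peak[-length(peak)])
  peak_at <- cummax(ifelse(new_peak, seq_along(v), 0L))
  armed <- peak > cfg$force_min_peak
  recent <- (seq_along(v) - peak_at) * dt <= cfg$force_drop_window + eps
  drop <- armed & recent & (v < cfg$force_drop_fraction * peak)
  i <- which(drop)
  if (length(i) == 0L) {
    withdrawal_result(FALSE, stim$cutoff, TRUE, stim$cutoff, "force",
                      threshold_force = NA_real_)
  } else {
    i <- i[1L]
    lat <- t[post[peak_at[i]]] - stim$onset
    withdrawal_result(TRUE, lat, FALSE, stim$cutoff, "force",
                      threshold_force = peak[i])
  }
}
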