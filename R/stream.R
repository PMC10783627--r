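#' Streaming withdrawal detector
#'
#' Incremental, sample-by-sample version of
#' [detect_withdrawal_reflectance()], suitable for real-time closed-loop
#' termination of the stimulus. The state maintains the trailing-window
#' running mean, accumulates the pre-stimulus baseline, and tracks the
#' current sub-threshold run; the moment the persistence criterion is
#' satisfied it emits a detection event whose latency points back to the
#' start of the run (the crossing sample). On identical samples it is
#' guaranteed to return exactly the offline detector's result.
#'
#' @param stim A [stimulus_event()].
#' @param cfg A [detection_config()].
#' @param fs Sampling rate of the incoming samples (Hz).
#' @param units Units of the incoming samples (default `"mV"`).
#' @return A detector state (environment) of class `stream_detector`.
#' @seealso [stream_push()], [stream_finalize()], [stream_replay()]
#' @export
stream_detector <- function(stim, cfg = detection_config(), fs = 1000,
                            units = "mV") {
  stopifnot(inherits(stim, "stimulus_event"), inherits(cfg, "detection_config"))
  st <- new.env(parent = emptyenv())
  st$n <- window_samples(cfg$smooth_window, fs)
  st$buf <- numeric(st$n)
  st$nbuf <- 0L
  st$pos <- 1L
  st$bufsum <- 0
  st$dt <- 1000 / fs
  st$eps <- st$dt * 1e-6
  st$last_t <- -Inf
  st$onset <- stim$onset
  st$cutoff_t <- stim$onset + stim$cutoff
  st$base_from <- stim$onset - cfg$baseline_window
  st$base_sum <- 0
  st$base_n <- 0L
  st$threshold <- NA_real_
  st$baseline <- NA_real_
  st$persistence <- cfg$persistence
  st$drop <- cfg$reflectance_drop
  st$run_len <- 0L
  st$run_start <- NA_real_
  st$done <- FALSE
  st$event <- NULL
  st$units <- units
  st$cutoff <- stim$cutoff
  class(st) <- "stream_detector"
  st
}

#' Push one sample into a streaming detector
#'
#' Samples must arrive in strictly increasing time order at the detector's
#' sampling rate. Returns the emitted [withdrawal_result()] the moment the
#' persistence criterion is met (with attribute `emitted_at`, the time of
#' emission — `persistence` ms after the crossing sample), a censored result
#' at the first sample past the cutoff, and `NULL` otherwise.
#'
#' @param st A [stream_detector()] state.
#' @param t Sample time in ms.
#' @param v Sample value.
#' @return `NULL`, or the emitted `withdrawal_result`.
#' @export
stream_push <- function(st, t, v) {
  if (t <= st$last_t + st$eps) {
    stop("out-of-order sample: t = ", t, " after ", st$last_t)
  }
  st$last_t <- t
  # trailing truncated mean, identical to smooth_running_average()
  if (st$nbuf < st$n) {
    st$nbuf <- st$nbuf + 1L
    st$bufsum <- st$bufsum + v
    st$buf[st$nbuf] <- v
    if (st$nbuf == st$n) st$pos <- 1L
  } else {
    st$bufsum <- st$bufsum + v - st$buf[st$pos]
    st$buf[st$pos] <- v
    st$pos <- if (st$pos == st$n) 1L else st$pos + 1L
  }
  sm <- st$bufsum / st$nbuf
  if (st$done) return(invisible(NULL))
  if (t >= st$base_from - st$eps && t < st$onset - st$eps) {
    st$base_sum <- st$base_sum + sm
    st$base_n <- st$base_n + 1L
    return(invisible(NULL))
  }
  if (t <= st$onset + st$eps) return(invisible(NULL))
  if (t > st$cutoff_t + st$eps) {
    return(invisible(stream_finalize(st)))
  }
  if (is.na(st$threshold)) {
    if (st$base_n == 0L) stop("no baseline samples seen before onset")
    st$baseline <- st$base_sum / st$base_n
    st$threshold <- st$baseline - st$drop
  }
  if (sm < st$threshold) {
    if (st$run_len == 0L) st$run_start <- t
    st$run_len <- st$run_len + 1L
    if (st$run_len * st$dt > st$persistence) {
      st$done <- TRUE
      ev <- withdrawal_result(TRUE, st$run_start - st$onset, FALSE,
                              st$cutoff, "reflectance")
      attr(ev, "emitted_at") <- t
      st$event <- ev
      return(invisible(ev))
    }
  } else {
    st$run_len <- 0L
    st$run_start <- NA_real_
  }
  invisible(NULL)
}

#' Finalize a streaming detector
#'
#' Call after the last sample (or at the cutoff) to obtain the result for a
#' trial on which no event was emitted: a censored [withdrawal_result()] at
#' the stimulus cutoff. Returns the already-emitted event if there was one.
#'
#' @param st A [stream_detector()] state.
#' @return A [withdrawal_result()].
#' @export
stream_finalize <- function(st) {
  if (!st$done) {
    st$done <- TRUE
    ev <- withdrawal_result(FALSE, st$cutoff, TRUE, st$cutoff, "reflectance")
    attr(ev, "emitted_at") <- st$cutoff_t
    st$event <- ev
  }
  st$event
}

#' Replay a full trace through the streaming detector
#'
#' Convenience driver (and the offline-equivalence oracle hook): pushes every
#' sample of `trace` in order and finalizes. The result is identical to
#' [detect_withdrawal_reflectance()] on the same trace.
#'
#' @param trace Reflectance [signal_trace()] in mV.
#' @param stim A [stimulus_event()].
#' @param cfg A [detection_config()].
#' @return A [withdrawal_result()] with attribute `emitted_at` (ms): the
#'   time at which the closed-loop event fired (detection) or the cutoff
#'   (censoring).
#' @export
stream_replay <- function(trace, stim, cfg = detection_config()) {
  stopifnot(inherits(trace, "signal_trace"))
  if (trace$units != "mV") stop("reflectance trace must be in mV")
  st <- stream_detector(stim, cfg, fs = trace$fs, units = trace$units)
  tms <- trace_times(trace)
  v <- trace$values
  for (k in seq_along(v)) {
    ev <- stream_push(st, tms[k], v[k])
    if (!is.null(ev)) return(ev)
  }
  stream_finalize(st)
}
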