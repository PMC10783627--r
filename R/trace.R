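#' Uniformly sampled signal trace
#'
#' A `signal_trace` carries one channel of rig data: photodetector
#' reflectance (mV), indenter force (mN), paw height (px) or delivered
#' optical power (mW), sampled uniformly at `fs` Hz starting at `t0` ms.
#' Sample `k` (1-based) maps to time `t0 + (k - 1) * 1000 / fs` ms.
#'
#' @param values Numeric vector of samples; must be finite, length >= 1.
#' @param fs Sampling rate in Hz (default 1000, the rig's DAQ rate).
#' @param t0 Time of the first sample in ms (default 0).
#' @param units Physical units, one of `"mV"`, `"mN"`, `"px"`, `"mW"`.
#' @return An object of class `signal_trace`.
#' @examples
#' tr <- signal_trace(rep(100, 1000), fs = 1000, units = "mV")
#' head(trace_times(tr))
#' @export
signal_trace <- function(values, fs = 1000, t0 = 0,
                         units = c("mV", "mN", "px", "mW")) {
  units <- match.arg(units)
  values <- as.numeric(values)
  if (length(values) < 1L) stop("trace must contain at least one sample")
  if (!all(is.finite(values))) stop("trace values must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be > 0")
  structure(list(values = values, fs = fs, t0 = t0, units = units),
            class = "signal_trace")
}

#' Sample times of a trace
#'
#' @param trace A [signal_trace()].
#' @return Numeric vector of sample times in ms.
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "signal_trace"))
  trace$t0 + (seq_along(trace$values) - 1) * (1000 / trace$fs)
}

#' @export
length.signal_trace <- function(x) length(x$values)

#' @export
print.signal_trace <- function(x, ...) {
  dur <- (length(x$values) - 1) * 1000 / x$fs
  cat(sprintf("<signal_trace> %d samples @ %g Hz, t0 = %g ms (%.1f ms), units %s\n",
              length(x$values), x$fs, x$t0, dur, x$units))
  invisible(x)
}

# ms -> whole samples at fs, nearest count, floor 1 (realized width may differ
# from the requested one at rates other than 1 kHz; it is recorded on the
# smoothed trace)
window_samples <- function(window_ms, fs) {
  max(1L, as.integer(round(window_ms * fs / 1000)))
}

#' Trailing running-average smoothing
#'
#' Causal (trailing) boxcar mean: sample `k` of the output is the mean of the
#' input over the window of `window` ms ending at `k`, truncated at the trace
#' start (so the first output sample equals the first input sample). The
#' causal alignment is what permits an identical streaming implementation for
#' closed-loop use; see [stream_detector()].
#'
#' @param trace A [signal_trace()].
#' @param window Window width in ms (default 27, the reflectance-denoising
#'   width used at 1 kHz). Converted to the nearest whole number of samples.
#' @return A `signal_trace` of equal length; attributes `smooth_samples` and
#'   `smooth_window_ms` record the realized window.
#' @examples
#' tr <- signal_trace(c(rep(10, 50), rep(0, 50)), units = "mV")
#' sm <- smooth_running_average(tr, 27)
#' @export
smooth_running_average <- function(trace, window = 27) {
  stopifnot(inherits(trace, "signal_trace"))
  n <- window_samples(window, trace$fs)
  if (n > length(trace$values)) stop("window exceeds trace")
  v <- trace$values
  cs <- cumsum(v)
  k <- seq_along(v)
  num <- cs - c(rep(0, min(n, length(v))), cs)[k] # cs[k] - cs[k-n], 0 when k<=n
  den <- pmin(k, n)
  out <- trace
  out$values <- num / den
  attr(out, "smooth_samples") <- n
  attr(out, "smooth_window_ms") <- n * 1000 / trace$fs
  out
}

#' Pre-stimulus baseline level
#'
#' Mean of the samples in the half-open epoch `[onset - window, onset)`,
#' i.e. the `window` ms immediately preceding stimulus onset.
#'
#' @param trace A [signal_trace()].
#' @param onset Stimulus onset time in ms.
#' @param window Baseline epoch width in ms (default 500).
#' @return Baseline level in the trace's units.
#' @export
baseline_level <- function(trace, onset, window = 500) {
  stopifnot(inherits(trace, "signal_trace"))
  dt <- 1000 / trace$fs
  eps <- dt * 1e-6
  if (onset - window < trace$t0 - eps) stop("baseline window not covered")
  t <- trace_times(trace)
  sel <- t >= onset - window - eps & t < onset - eps
  if (!any(sel)) stop("baseline window not covered")
  mean(trace$values[sel])
}
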