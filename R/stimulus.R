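#' Stimulus event descriptor
#'
#' Describes one stimulus applied to the paw: the modality (optogenetic blue
#' pulse, radiant-heat thermal, or mechanical indenter ramp), the waveform,
#' the onset time relative to the associated traces, the intensity, and the
#' cutoff after which an undetected trial is censored.
#'
#' @param modality One of `"optogenetic"`, `"thermal"`, `"mechanical"`.
#' @param waveform One of `"pulse"`, `"ramp"`, `"custom"`.
#' @param onset Onset time in ms.
#' @param intensity Stimulus intensity: mW for optogenetic pulses, mN/s for
#'   mechanical ramps, arbitrary laser-power units for thermal.
#' @param cutoff Maximum stimulus duration in ms (default 20000, the
#'   thermal-assay cutoff); trials with no detected withdrawal by
#'   `onset + cutoff` are censored.
#' @param wavelength_nm Optional wavelength metadata (455 blue, 625 red,
#'   980 IR).
#' @return An object of class `stimulus_event`.
#' @export
stimulus_event <- function(modality = c("optogenetic", "thermal", "mechanical"),
                           waveform = c("pulse", "ramp", "custom"),
                           onset = 0, intensity = 1, cutoff = 20000,
                           wavelength_nm = NA_real_) {
  modality <- match.arg(modality)
  waveform <- match.arg(waveform)
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (intensity < 0) stop("intensity must be >= 0")
  structure(list(modality = modality, waveform = waveform, onset = onset,
                 intensity = intensity, cutoff = cutoff,
                 wavelength_nm = wavelength_nm),
            class = "stimulus_event")
}

#' Withdrawal-detection configuration
#'
#' Parameters of the three withdrawal detectors. Defaults are the values used
#' for all rig measurements: a 0.5 s pre-stimulus baseline epoch, a 27 ms
#' running-average window, a 2 mV reflectance drop criterion with a > 20 ms
#' persistence requirement, and a 6 px paw-height rise criterion. The
#' mechanical-drop parameters (`force_drop_fraction`, `force_drop_window`,
#' `force_min_peak`) operationalize the "abrupt drop in force" at withdrawal:
#' the force must fall strictly below `force_drop_fraction` of the running
#' peak within `force_drop_window` ms of that peak, and the rule is armed
#' only once the running peak exceeds `force_min_peak` (so sensor noise on a
#' near-zero force cannot masquerade as a drop).
#'
#' @param baseline_window Baseline epoch in ms (default 500).
#' @param smooth_window Running-average width in ms (default 27).
#' @param reflectance_drop Threshold depth below baseline in mV (default 2).
#' @param persistence Minimum sub-threshold duration in ms; the run must last
#'   strictly longer (default 20, i.e. >= 21 samples at 1 kHz).
#' @param height_rise Paw-height rise criterion in px (default 6).
#' @param height_smooth_window Optional smoothing for the height channel in
#'   ms; `NULL` (default) applies none.
#' @param force_drop_fraction Fraction of the running peak force below which
#'   a drop counts as withdrawal (default 0.5).
#' @param force_drop_window Maximum time from running peak to drop in ms
#'   (default 50).
#' @param force_min_peak Minimum running peak in mN before the drop rule is
#'   armed (default 5).
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(baseline_window = 500, smooth_window = 27,
                             reflectance_drop = 2, persistence = 20,
                             height_rise = 6, height_smooth_window = NULL,
                             force_drop_fraction = 0.5,
                             force_drop_window = 50,
                             force_min_peak = 5) {
  num <- c(baseline_window = baseline_window, smooth_window = smooth_window,
           reflectance_drop = reflectance_drop, persistence = persistence,
           height_rise = height_rise,
           force_drop_fraction = force_drop_fraction,
           force_drop_window = force_drop_window)
  if (any(num <= 0)) {
    stop("detection parameters must be positive: ",
         paste(names(num)[num <= 0], collapse = ", "))
  }
  if (force_drop_fraction > 1) stop("force_drop_fraction must be in (0, 1]")
  if (force_min_peak < 0) stop("force_min_peak must be >= 0")
  structure(list(baseline_window = baseline_window,
                 smooth_window = smooth_window,
                 reflectance_drop = reflectance_drop,
                 persistence = persistence,
                 height_rise = height_rise,
                 height_smooth_window = height_smooth_window,
                 force_drop_fraction = force_drop_fraction,
                 force_drop_window = force_drop_window,
                 force_min_peak = force_min_peak),
            class = "detection_config")
}

#' @export
print.detection_config <- function(x, ...) {
  cat("<detection_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-21s %s\n", nm,
                if (is.null(x[[nm]])) "none" else format(x[[nm]])))
  }
  invisible(x)
}
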