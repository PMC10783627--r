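#' Session plan for interleaved multi-animal testing
#'
#' Describes one testing session: which animals, how many trials each, the
#' per-animal inter-stimulus interval, and whether the within-round testing
#' order is randomized. By interleaving, other animals are tested during
#' each animal's inter-stimulus interval.
#'
#' @param mouse_ids Character vector of animal identifiers (>= 1).
#' @param trials_per_mouse Trials per animal (rounds).
#' @param interval_s Minimum inter-stimulus interval per animal in seconds.
#' @param seed Randomization seed for the per-round testing order.
#' @param randomize Randomize the order each round (default TRUE).
#' @param interleave Interleave animals within a round (default TRUE);
#'   FALSE tests each animal's trials back to back, which forces waiting
#'   out the full interval between its trials.
#' @return An object of class `session_plan`.
#' @export
session_plan <- function(mouse_ids, trials_per_mouse = 1, interval_s = 60,
                         seed = 1, randomize = TRUE, interleave = TRUE) {
  mouse_ids <- as.character(mouse_ids)
  if (length(mouse_ids) < 1L) stop("need at least one mouse")
  if (anyDuplicated(mouse_ids)) stop("mouse_ids must be unique")
  if (interval_s <= 0) stop("interval must be > 0")
  if (trials_per_mouse < 1) stop("trials_per_mouse must be >= 1")
  structure(list(mouse_ids = mouse_ids, trials_per_mouse = trials_per_mouse,
                 interval_s = interval_s, seed = seed,
                 randomize = randomize, interleave = interleave),
            class = "session_plan")
}

#' Run one closed-loop virtual trial
#'
#' Full trial pipeline against the virtual rig: a key-point stream is
#' generated and aimed at ([run_aiming()]); if aiming succeeds, the
#' photostimulus starts, the simulated reflectance trace is fed through the
#' streaming detector ([stream_replay()]), and the stimulus is terminated
#' at the detection event or the cutoff, whichever comes first. The trial
#' record carries the measurements, seeds and a hash of the resolved
#' configuration.
#'
#' @param rig A [virtual_rig()].
#' @param stim A [stimulus_event()]; its onset is interpreted relative to
#'   the trial's trace (the pre-onset span equals the detection baseline
#'   window).
#' @param cfg A [controller_config()].
#' @param det A [detection_config()].
#' @param seed Trial seed; defaults to the rig seed.
#' @param epoch_ms Session clock (ms) at which this trial starts; used for
#'   the record timestamp.
#' @param epoch Origin of the simulated session clock (POSIXct, UTC).
#' @return A list of class `trial_run`: `record` (one-row data.frame in the
#'   session-log schema), `detection` (the [withdrawal_result()] or NULL),
#'   `aiming` (the `aiming_run`), `stim_duration_ms`, `trace` and
#'   `keypoints`.
#' @export
run_trial <- function(rig, stim, cfg = controller_config(),
                      det = detection_config(), seed = NULL, epoch_ms = 0,
                      epoch = as.POSIXct("2026-01-01 00:00:00", tz = "UTC")) {
  stopifnot(inherits(rig, "virtual_rig"), inherits(stim, "stimulus_event"))
  if (is.null(seed)) seed <- rig$seed
  kp_seed <- derive_seed(seed, "keypoints")
  tr_seed <- derive_seed(seed, "trace")
  stream <- simulate_keypoints(motion = rig$motion,
                               bout_params = rig$bout_params, fps = rig$fps,
                               duration = cfg$giveup_period + 1000,
                               noise_px = rig$noise_px, seed = kp_seed,
                               arena = rig$arena)
  aimed <- run_aiming(stream, cfg)
  chash <- config_hash(list(controller = unclass(cfg),
                            detection = lapply(unclass(det), function(x) {
                              if (is.null(x)) "none" else x
                            })))
  base <- list(mouse_id = rig$mouse_id, timestamp = NA_character_,
               modality = stim$modality, waveform = stim$waveform,
               intensity = stim$intensity, cutoff_ms = stim$cutoff,
               outcome = NA_character_, latency_ms = NA_real_,
               censored = FALSE, threshold_mN = NA_real_, seed = seed,
               config_hash = chash, trace_path = "", keypoints_path = "")
  if (aimed$outcome == "SKIPPED") {
    onset_ms <- epoch_ms + aimed$history$time_ms[aimed$frames]
    base$timestamp <- format(epoch + onset_ms / 1000,
                             "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
    base$outcome <- "skipped"
    rec <- as.data.frame(base, stringsAsFactors = FALSE)
    return(structure(list(record = rec, detection = NULL, aiming = aimed,
                          stim_duration_ms = 0, trace = NULL,
                          keypoints = stream),
                     class = "trial_run"))
  }
  trial_stim <- stim
  trial_stim$onset <- det$baseline_window
  sim <- simulate_reflectance_trial(rig$paw, trial_stim, seed = tr_seed,
                                    baseline_pad = det$baseline_window)
  res <- stream_replay(sim$trace, trial_stim, det)
  emitted <- attr(res, "emitted_at")
  stim_duration <- min(emitted - trial_stim$onset, stim$cutoff)
  onset_ms <- epoch_ms + aimed$stim_time
  base$timestamp <- format(epoch + onset_ms / 1000,
                           "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
  base$outcome <- if (res$detected) "detected" else "censored"
  base$latency_ms <- res$latency
  base$censored <- res$censored
  rec <- as.data.frame(base, stringsAsFactors = FALSE)
  structure(list(record = rec, detection = res, aiming = aimed,
                 stim_duration_ms = stim_duration, trace = sim$trace,
                 keypoints = stream),
            class = "trial_run")
}

#' Run an interleaved virtual session
#'
#' Schedules and executes `trials_per_mouse` rounds over all animals. The
#' order within each round is a (seeded) random permutation of the animals;
#' the session clock advances through aiming, stimulation and the move to
#' the next enclosure, and no animal is stimulated again before its
#' inter-stimulus interval has elapsed — the scheduler waits when
#' interleaving alone does not cover the interval.
#'
#' @param plan A [session_plan()].
#' @param rigs List of [virtual_rig()]s, one per animal in
#'   `plan$mouse_ids` (names must match).
#' @param stim A [stimulus_event()] applied on every trial.
#' @param cfg A [controller_config()].
#' @param det A [detection_config()].
#' @param move_ms Time to translate to the next enclosure in ms
#'   (default 2000).
#' @param epoch Origin of the simulated session clock.
#' @return A list of class `session_run`: `log` (data.frame of trial
#'   records in schedule order, plus `onset_ms`, the simulated per-trial
#'   stimulus-onset clock) and `trials` (list of `trial_run`s).
#' @export
run_session <- function(plan, rigs, stim, cfg = controller_config(),
                        det = detection_config(), move_ms = 2000,
                        epoch = as.POSIXct("2026-01-01 00:00:00", tz = "UTC")) {
  stopifnot(inherits(plan, "session_plan"))
  ids <- plan$mouse_ids
  if (is.null(names(rigs))) names(rigs) <- vapply(rigs, `[[`, "", "mouse_id")
  if (!all(ids %in% names(rigs))) stop("missing rig for some mouse_ids")
  if (plan$interval_s * 1000 > cfg$giveup_period * length(ids) * 100) {
    message("note: long inter-stimulus interval relative to session pace; ",
            "the scheduler will spend most time waiting")
  }
  clock <- 0
  last_onset <- stats::setNames(rep(-Inf, length(ids)), ids)
  trials <- list()
  rows <- list()
  k <- 0L
  for (round in seq_len(plan$trials_per_mouse)) {
    order_ids <- if (plan$randomize) {
      with_seed(derive_seed(plan$seed, "round", round),
                sample(ids, length(ids)))
    } else ids
    for (m in order_ids) {
      k <- k + 1L
      # wait out the animal's inter-stimulus interval if interleaving has
      # not already covered it
      earliest <- last_onset[[m]] + plan$interval_s * 1000
      if (is.finite(earliest) && clock < earliest) clock <- earliest
      trial_seed <- derive_seed(plan$seed, m, round)
      tr <- run_trial(rigs[[m]], stim, cfg, det, seed = trial_seed,
                      epoch_ms = clock, epoch = epoch)
      aim_ms <- tr$aiming$history$time_ms[tr$aiming$frames] +
        1000 / rigs[[m]]$fps
      onset <- clock + if (tr$aiming$outcome == "STIMULATE") {
        tr$aiming$stim_time
      } else aim_ms
      if (tr$aiming$outcome == "STIMULATE") last_onset[[m]] <- onset
      row <- tr$record
      row$onset_ms <- onset
      rows[[k]] <- row
      trials[[k]] <- tr
      clock <- onset + tr$stim_duration_ms + move_ms
    }
  }
  log <- do.call(rbind, rows)
  rownames(log) <- NULL
  structure(list(log = log, trials = trials, plan = plan),
            class = "session_run")
}
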