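#' Write a signal trace to delimited text
#'
#' Two-column comma-separated file (`time_ms,value`) preceded by comment
#' headers declaring the format version, units, sampling rate and start
#' time. Values are written at full precision so that a read/write
#' round-trip is bit-identical.
#'
#' @param trace A [signal_trace()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "signal_trace"))
  t <- trace_times(trace)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("# nocirig trace v1",
               paste0("# units: ", trace$units),
               paste0("# fs: ", format_full(trace$fs)),
               paste0("# t0: ", format_full(trace$t0)),
               "time_ms,value"), con)
  writeLines(paste(format_full(t), format_full(trace$values), sep = ","), con)
  invisible(path)
}

#' Read a signal trace from delimited text
#'
#' Reads the format written by [write_trace()]. The header must declare
#' units and sampling rate; timestamps are checked for uniform sampling at
#' the declared rate to within 1 ppm, and the first offending row is named
#' otherwise.
#'
#' @param path File path.
#' @return A [signal_trace()].
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(key) {
    m <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (length(m) == 0) return(NULL)
    sub(paste0("^# ", key, ": "), "", m[1])
  }
  units <- get_field("units")
  if (is.null(units)) stop("trace header missing units")
  fs <- get_field("fs")
  if (is.null(fs)) stop("trace header missing fs")
  fs <- as.numeric(fs)
  body <- lines[!grepl("^#", lines)]
  if (length(body) < 2L || body[1] != "time_ms,value") {
    stop("malformed trace file: expected 'time_ms,value' header row")
  }
  dat <- utils::read.csv(text = body, header = TRUE)
  t <- dat$time_ms
  v <- dat$value
  dt <- 1000 / fs
  if (length(t) > 1L) {
    diffs <- diff(t)
    bad <- which(abs(diffs - dt) > dt * 1e-6)
    if (length(bad) > 0) {
      stop("non-uniform sampling (or fs mismatch) at row ", bad[1] + 1L,
           ": interval ", format(diffs[bad[1]]), " ms vs expected ",
           format(dt), " ms")
    }
  }
  signal_trace(v, fs = fs, t0 = t[1], units = units)
}

session_log_columns <- c("mouse_id", "timestamp", "modality", "waveform",
                         "intensity", "cutoff_ms", "outcome", "latency_ms",
                         "censored", "threshold_mN", "seed", "config_hash",
                         "trace_path", "keypoints_path")

#' Write a session log
#'
#' Serializes trial records to append-only comma-separated text with a
#' fixed column order and a header declaring the schema version. Censored
#' trials carry their censor time in `latency_ms` (never a blank). Linked
#' trace/key-point paths must exist at write time; duplicate
#' `(mouse_id, timestamp)` pairs are refused.
#'
#' @param records Data frame of trial records (see [run_trial()]); extra
#'   columns are ignored.
#' @param path Output file path.
#' @param append Append to an existing log (default FALSE).
#' @return `path`, invisibly.
#' @export
write_session_log <- function(records, path, append = FALSE) {
  records <- as.data.frame(records)
  missing_cols <- setdiff(session_log_columns, names(records))
  if (length(missing_cols) > 0) {
    stop("records missing columns: ", paste(missing_cols, collapse = ", "))
  }
  records <- records[, session_log_columns, drop = FALSE]
  key <- paste(records$mouse_id, records$timestamp)
  if (anyDuplicated(key)) {
    stop("duplicate (mouse_id, timestamp) in records")
  }
  for (col in c("trace_path", "keypoints_path")) {
    linked <- records[[col]][!is.na(records[[col]]) & records[[col]] != ""]
    missing_files <- linked[!file.exists(linked)]
    if (length(missing_files) > 0) {
      stop("linked file does not exist: ", missing_files[1])
    }
  }
  fmt <- records
  for (col in c("intensity", "cutoff_ms", "latency_ms", "threshold_mN")) {
    fmt[[col]] <- format_full(records[[col]])
  }
  fmt$censored <- ifelse(records$censored, "true", "false")
  fmt <- lapply(fmt, as.character)
  lines <- do.call(paste, c(fmt, sep = ","))
  if (append && file.exists(path)) {
    existing <- read_session_log(path)
    dup <- intersect(key, paste(existing$mouse_id, existing$timestamp))
    if (length(dup) > 0) {
      stop("duplicate (mouse_id, timestamp) vs existing log: ", dup[1])
    }
    cat(lines, file = path, sep = "\n", append = TRUE)
    cat("\n", file = path, append = TRUE)
  } else {
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines(c("# nocirig session log v1",
                 paste(session_log_columns, collapse = ","),
                 lines), con)
  }
  invisible(path)
}

#' Read a session log
#'
#' @param path File written by [write_session_log()].
#' @return Data frame of trial records.
#' @export
read_session_log <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  body <- lines[!grepl("^#", lines)]
  if (length(body) == 0L) stop("empty session log: ", path)
  dat <- utils::read.csv(text = body, header = TRUE,
                         colClasses = c(mouse_id = "character",
                                        timestamp = "character",
                                        intensity = "numeric",
                                        cutoff_ms = "numeric",
                                        latency_ms = "numeric",
                                        threshold_mN = "numeric",
                                        seed = "numeric",
                                        censored = "character",
                                        config_hash = "character",
                                        trace_path = "character",
                                        keypoints_path = "character"))
  if (!identical(names(dat), session_log_columns)) {
    stop("unexpected session log columns")
  }
  dat$censored <- dat$censored == "true"
  dat
}

#' Write a key-point stream to delimited text
#'
#' Long-format comma-separated table (`frame,time_ms,part,x_px,y_px,`
#' `confidence`) with comment headers recording fps and arena size.
#'
#' @param stream A `keypoint_stream` (see [simulate_keypoints()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_keypoints <- function(stream, path) {
  stopifnot(inherits(stream, "keypoint_stream"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("# nocirig keypoints v1",
               paste0("# fps: ", format_full(attr(stream, "fps"))),
               paste0("# arena: ", paste(attr(stream, "arena"),
                                         collapse = "x")),
               "frame,time_ms,part,x_px,y_px,confidence"), con)
  writeLines(paste(stream$frame, format_full(stream$time_ms), stream$part,
                   format_full(stream$x_px), format_full(stream$y_px),
                   format_full(stream$confidence), sep = ","), con)
  invisible(path)
}

#' Read a key-point stream
#'
#' @param path File written by [write_keypoints()].
#' @return A `keypoint_stream` data frame.
#' @export
read_keypoints <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  fps_line <- grep("^# fps: ", hdr, value = TRUE)
  if (length(fps_line) == 0) stop("keypoints header missing fps")
  fps <- as.numeric(sub("^# fps: ", "", fps_line[1]))
  arena_line <- grep("^# arena: ", hdr, value = TRUE)
  arena <- if (length(arena_line) > 0) {
    as.numeric(strsplit(sub("^# arena: ", "", arena_line[1]), "x")[[1]])
  } else c(640, 480)
  dat <- utils::read.csv(text = lines[!grepl("^#", lines)], header = TRUE)
  structure(dat, fps = fps, arena = arena,
            class = c("keypoint_stream", "data.frame"))
}

#' Read a rig configuration file
#'
#' Flat YAML key-value configuration covering detection, controller and
#' session settings. Missing keys fall back to the package defaults;
#' unknown keys are an error. Returns the resolved configuration objects
#' plus a stable hash of the resolved settings.
#'
#' @param path YAML file path, or NULL for all defaults.
#' @return A list with `detection` ([detection_config()]), `controller`
#'   ([controller_config()]), `session` (list of session settings) and
#'   `hash`.
#' @export
read_rig_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  det_args <- formals(detection_config)
  ctl_args <- formals(controller_config)
  ses_defaults <- list(mouse_ids = "m1", trials_per_mouse = 1,
                       interval_s = 60, true_latency = 150, noise_sd = 1,
                       cutoff_ms = 20000, intensity = 10)
  det <- list(); ctl <- list(); ses <- ses_defaults
  for (key in names(raw)) {
    if (key %in% names(det_args)) {
      det[[key]] <- raw[[key]]
    } else if (key %in% names(ctl_args)) {
      ctl[[key]] <- raw[[key]]
    } else if (key %in% names(ses_defaults)) {
      ses[[key]] <- raw[[key]]
    } else {
      stop("unknown configuration key: ", key)
    }
  }
  detection <- do.call(detection_config, det)
  controller <- do.call(controller_config, ctl)
  resolved <- list(detection = lapply(unclass(detection), function(x) {
    if (is.null(x)) "none" else x
  }),
  controller = unclass(controller), session = ses)
  list(detection = detection, controller = controller, session = ses,
       hash = config_hash(resolved))
}
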