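#' Setting signals
#'
#' Setting signals are the parameter-update messages flowing to the
#' necklace from the phone or the calibration computer: calibrate a
#' standard value, move an adjustment slider, change the reminder
#' frequency, or connect/disconnect the phone. Each signal is one line of
#' structured text (compact JSON), and [decode_signal()] inverts
#' [encode_signal()] exactly.
#'
#' @param kind one of `calibrate_S_x`, `calibrate_S_y`,
#'   `set_warning_time`, `set_FW_center`, `set_FW_limit`,
#'   `set_LR_center`, `set_LR_limit`, `connect`, `disconnect`.
#' @param value the payload: a slider position in `[1, 300]` for the
#'   slider kinds, a positive integer for `set_warning_time`, a value in
#'   G for the calibrate kinds; `connect`/`disconnect` carry none.
#' @param t optional timestamp (seconds) used when scripting signals
#'   into a session.
#' @return An object of class `setting_signal`.
#' @export
#' @examples
#' decode_signal(encode_signal(setting_signal("set_FW_center", 200)))
setting_signal <- function(kind, value = NULL, t = NULL) {
  kinds <- c("calibrate_S_x", "calibrate_S_y", "set_warning_time",
             "set_FW_center", "set_FW_limit", "set_LR_center",
             "set_LR_limit", "connect", "disconnect")
  if (!kind %in% kinds) stop("unknown signal kind: ", kind, call. = FALSE)
  slider_kinds <- c("set_FW_center", "set_FW_limit", "set_LR_center",
                    "set_LR_limit")
  if (kind %in% slider_kinds) {
    if (is.null(value) || value < 1 || value > 300 ||
        value != round(value)) {
      stop(kind, " requires an integer value in [1, 300]", call. = FALSE)
    }
    value <- as.integer(value)
  }
  if (kind == "set_warning_time") {
    if (is.null(value) || value < 1 || value != round(value)) {
      stop("set_warning_time requires a positive integer", call. = FALSE)
    }
    value <- as.integer(value)
  }
  if (kind %in% c("connect", "disconnect")) value <- NULL
  structure(list(kind = kind, value = value, t = t),
            class = "setting_signal")
}

#' @rdname setting_signal
#' @param signal a `setting_signal`.
#' @export
encode_signal <- function(signal) {
  payload <- list(kind = signal$kind)
  if (!is.null(signal$value)) payload$value <- signal$value
  if (!is.null(signal$t)) payload$t <- signal$t
  as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA))
}

#' @rdname setting_signal
#' @param line one encoded line.
#' @export
decode_signal <- function(line) {
  payload <- tryCatch(jsonlite::fromJSON(line),
                      error = function(e) {
                        stop("malformed signal line: ", line, call. = FALSE)
                      })
  if (is.null(payload$kind)) {
    stop("malformed signal line (no kind): ", line, call. = FALSE)
  }
  setting_signal(payload$kind, payload$value, payload$t)
}

#' Session configuration
#'
#' @param duration session operating time, seconds; the assessment loop
#'   stops when it is reached. Default 8 hours.
#' @param sample_rate accelerometer sampling rate, Hz; default 10.
#' @param warning_time reminder-frequency setting (higher = more
#'   frequent); default 1.
#' @param window moving-average filter window, samples; default 10.
#' @param hold_frames,tol_deg auto-calibration debounce and geometric
#'   tolerance (see [auto_calibrate()]).
#' @param connected whether the phone starts connected; reminders are
#'   delivered only while connected. Default TRUE.
#' @param T0 base reminder throttle period, seconds; default 10.
#' @return An object of class `session_config`.
#' @export
session_config <- function(duration = 8 * 3600, sample_rate = 10,
                           warning_time = 1, window = 10, hold_frames = 5,
                           tol_deg = 2.0, connected = TRUE, T0 = 10) {
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  if (warning_time < 1 || warning_time != round(warning_time)) {
    stop("warning_time must be a positive integer", call. = FALSE)
  }
  structure(list(duration = duration, sample_rate = sample_rate,
                 warning_time = as.integer(warning_time), window = window,
                 hold_frames = hold_frames, tol_deg = tol_deg,
                 connected = connected, T0 = T0),
            class = "session_config")
}

#' Run a full monitoring session
#'
#' Orchestrates the three-phase workflow: auto-calibration from the
#' keypoint stream (primary mechanism), application of any scripted
#' slider adjustments (secondary mechanism), then the assessment loop,
#' which feeds the filtered trace through the comparators and emits
#' throttled reminders while the phone is connected. Scripted signals
#' with timestamps are applied as the loop passes their time. The run
#' terminates at `config$duration` or the end of the trace, whichever
#' comes first.
#'
#' @param config a [session_config()].
#' @param trace an [accel_trace()] covering the session.
#' @param keypoints a `keypoint_frames` stream for the calibration
#'   phase, or `NULL` when `thresholds` is given.
#' @param signals optional list of [setting_signal()]s; those with a
#'   timestamp `t` are applied mid-session, those without immediately
#'   after calibration.
#' @param thresholds optional pre-built `threshold_set`, bypassing
#'   auto-calibration (e.g. loaded from file).
#' @param offsets optional offsets override for the threshold build.
#' @return An object of class `session_log`: list with `log` (data frame
#'   of timestamped entries: type, detail), `events` (reminder events),
#'   `thresholds` (final `threshold_set`), and `calibration`.
#' @export
run_session <- function(config, trace, keypoints = NULL, signals = list(),
                        thresholds = NULL, offsets = NULL) {
  log_t <- numeric(0); log_type <- character(0); log_detail <- character(0)
  note <- function(t, type, detail = "") {
    log_t <<- c(log_t, t); log_type <<- c(log_type, type)
    log_detail <<- c(log_detail, detail)
  }

  filtered <- moving_average_filter(trace, window = config$window)

  # --- calibration phase (primary mechanism) ---
  t_ready <- 0
  calib <- NULL
  if (is.null(thresholds)) {
    if (is.null(keypoints)) {
      stop("uncalibrated session: supply keypoints or a threshold set",
           call. = FALSE)
    }
    calib <- auto_calibrate(keypoints, filtered,
                            hold_frames = config$hold_frames,
                            tol_deg = config$tol_deg)
    if (calib$status != "complete") {
      stop("uncalibrated session: auto-calibration ended with status '",
           calib$status, "'", call. = FALSE)
    }
    note(calib$t_S_x, "calibration", sprintf("S_x = %.5f", calib$S_x))
    note(calib$t_S_y, "calibration", sprintf("S_y = %.5f", calib$S_y))
    note(calib$t_S_y, "calibration-complete", "")
    thresholds <- build_threshold_set(calib$S_x, calib$S_y,
                                      offsets = offsets)
    t_ready <- calib$t_S_y
  } else {
    note(0, "calibration-loaded", "threshold set supplied")
  }

  # --- untimed signals: manual fine adjustment before assessment ---
  warning_time <- config$warning_time
  connected <- config$connected
  immediate <- Filter(function(s) is.null(s$t), signals)
  timed <- Filter(function(s) !is.null(s$t), signals)
  for (s in immediate) {
    applied <- apply_signal(s, thresholds, warning_time, connected,
                            filtered, t_ready)
    thresholds <- applied$thresholds; warning_time <- applied$warning_time
    connected <- applied$connected
    note(t_ready, "setting", signal_label(s))
  }
  if (length(timed) > 0) {
    ord <- order(vapply(timed, function(s) s$t, numeric(1)))
    timed <- timed[ord]
  }

  # --- assessment loop ---
  cmps <- build_comparators(thresholds)
  interval <- config$T0 / warning_time
  ev_t <- numeric(0); ev_flags <- list(); ev_msg <- character(0)
  last_t <- -Inf; last_flags <- character(0)
  prev_flags <- character(0)
  sig_i <- 1L
  for (k in seq_len(nrow(filtered))) {
    t <- filtered$t_s[k]
    if (t > config$duration) break
    if (t <= t_ready) next
    while (sig_i <= length(timed) && timed[[sig_i]]$t <= t) {
      s <- timed[[sig_i]]
      applied <- apply_signal(s, thresholds, warning_time, connected,
                              filtered, t)
      rebuilt <- !identical(applied$thresholds, thresholds)
      thresholds <- applied$thresholds
      warning_time <- applied$warning_time
      interval <- config$T0 / warning_time
      connected <- applied$connected
      if (rebuilt) cmps <- rebuild_preserving(cmps, thresholds)
      note(t, "setting", signal_label(s))
      sig_i <- sig_i + 1L
    }
    res <- assess(filtered$A_x[k], filtered$A_y[k], cmps,
                  S_y = thresholds$S_y)
    cmps <- res$comparators
    flags <- res$state$flags
    if (!identical(flags, prev_flags)) {
      note(t, "state-change",
           if (length(flags) == 0L) "flags cleared"
           else paste(flags, collapse = "+"))
      prev_flags <- flags
    }
    if (length(flags) == 0L) {
      last_flags <- character(0); last_t <- -Inf
    } else if (connected &&
               (!identical(flags, last_flags) || t - last_t >= interval)) {
      ev_t <- c(ev_t, t)
      ev_flags <- c(ev_flags, list(flags))
      ev_msg <- c(ev_msg, res$state$message)
      note(t, "reminder", res$state$message)
      last_t <- t; last_flags <- flags
    }
  }
  note(min(max(filtered$t_s), config$duration), "session-end", "")

  events <- data.frame(t_s = ev_t, message = ev_msg,
                       stringsAsFactors = FALSE)
  events$flags <- ev_flags
  log <- data.frame(t_s = log_t, type = log_type, detail = log_detail,
                    stringsAsFactors = FALSE)
  log <- log[order(log$t_s, seq_len(nrow(log))), ]
  rownames(log) <- NULL
  structure(list(log = log, events = events[, c("t_s", "flags", "message")],
                 thresholds = thresholds, calibration = calib),
            class = "session_log")
}

# apply one setting signal to the running session state
apply_signal <- function(s, thresholds, warning_time, connected,
                         filtered, t) {
  switch(s$kind,
    connect = { connected <- TRUE },
    disconnect = { connected <- FALSE },
    set_warning_time = { warning_time <- s$value },
    set_FW_center = { thresholds <- apply_sliders(thresholds, a = s$value) },
    set_FW_limit = { thresholds <- apply_sliders(thresholds, b = s$value) },
    set_LR_center = { thresholds <- apply_sliders(thresholds, c = s$value) },
    set_LR_limit = { thresholds <- apply_sliders(thresholds, d = s$value) },
    calibrate_S_x = {
      v <- filtered_at(filtered, t)
      thresholds <- build_threshold_set(v$A_x, thresholds$S_y,
                                        offsets = thresholds$offsets)
    },
    calibrate_S_y = {
      v <- filtered_at(filtered, t)
      thresholds <- build_threshold_set(thresholds$S_x, v$A_y,
                                        offsets = thresholds$offsets)
    })
  list(thresholds = thresholds, warning_time = warning_time,
       connected = connected)
}

# rebuild comparators after a threshold change, keeping current outputs
rebuild_preserving <- function(cmps, th) {
  new <- build_comparators(th)
  for (nm in names(new)) new[[nm]]$out <- cmps[[nm]]$out
  new
}

signal_label <- function(s) {
  if (is.null(s$value)) s$kind else paste(s$kind, s$value)
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf("Session log: %d entries, %d reminder(s)\n",
              nrow(x$log), nrow(x$events)))
  counts <- table(x$log$type)
  for (nm in names(counts)) cat(sprintf("  %s: %d\n", nm, counts[[nm]]))
  invisible(x)
}
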