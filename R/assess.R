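#' Posture state from active tilt flags
#'
#' Maps the set of active tilt flags onto the indicator LEDs and the
#' reminder message the wearer's phone displays. The middle LED is lit if
#' and only if no flag is active; a forward tilt lights the top LED, a
#' left or right tilt the corresponding side LED. Messages name the
#' forward direction first, then the lateral one, e.g.
#' `"Too Forward & Left!!"`.
#'
#' @param flags character vector, a subset of
#'   `c("forward", "left", "right")`; left and right are mutually
#'   exclusive.
#' @return An object of class `posture_state`: list with `flags`, `led`
#'   (indicator set), and `message` (`NA` when posture is correct).
#' @export
#' @examples
#' posture_state(c("forward", "left"))$message
posture_state <- function(flags = character()) {
  flags <- unique(as.character(flags))
  bad <- setdiff(flags, c("forward", "left", "right"))
  if (length(bad) > 0L) {
    stop("unknown flag(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (all(c("left", "right") %in% flags)) {
    stop("left and right flags are mutually exclusive", call. = FALSE)
  }
  # canonical order: forward first, then lateral
  flags <- intersect(c("forward", "left", "right"), flags)
  led <- if (length(flags) == 0L) "middle" else
    unname(c(forward = "top", left = "left", right = "right")[flags])
  message <- if (length(flags) == 0L) NA_character_ else
    paste0("Too ", paste(tools_title(flags), collapse = " & "), "!!")
  structure(list(flags = flags, led = led, message = message),
            class = "posture_state")
}

tools_title <- function(x) {
  paste0(toupper(substring(x, 1, 1)), substring(x, 2))
}

#' @export
print.posture_state <- function(x, ...) {
  if (length(x$flags) == 0L) {
    cat("posture: correct (middle LED)\n")
  } else {
    cat(sprintf("posture: %s (LED: %s) message: %s\n",
                paste(x$flags, collapse = "+"),
                paste(x$led, collapse = "+"), x$message))
  }
  invisible(x)
}

#' Assess one filtered sample against the three comparators
#'
#' Feeds the filtered spine-axis value `A_x` to the forward comparator
#' and the filtered lateral value `A_y` to the left and right
#' comparators, then assembles the composite posture state from the
#' comparator outputs. If both lateral comparators report poor posture at
#' once (possible only transiently with pathological thresholds), the
#' flag matching the side of the standard value the input actually lies
#' on wins: `A_y > S_y` keeps left, `A_y < S_y` keeps right — a physical
#' tilt cannot be leftward and rightward at the same time.
#'
#' @param A_x,A_y filtered axis values, G.
#' @param comparators list of three comparators from
#'   [build_comparators()].
#' @param S_y the lateral standard value, used only to break a
#'   left/right tie; default midway between the two lateral trigger
#'   thresholds.
#' @return List with `comparators` (updated states) and `state`
#'   (a [posture_state()]).
#' @export
assess <- function(A_x, A_y, comparators,
                   S_y = (comparators$left$href + comparators$right$href) / 2) {
  comparators$forward <- comparator_step(comparators$forward, A_x)
  comparators$left    <- comparator_step(comparators$left, A_y)
  comparators$right   <- comparator_step(comparators$right, A_y)
  flags <- names(comparators)[vapply(comparators, function(s) s$out == 1L,
                                     logical(1))]
  if (all(c("left", "right") %in% flags)) {
    drop <- if (A_y > S_y) "right" else if (A_y < S_y) "left" else
      c("left", "right")
    flags <- setdiff(flags, drop)
  }
  list(comparators = comparators, state = posture_state(flags))
}

#' Assess a whole filtered trace
#'
#' Runs [assess()] over every sample of a filtered trace, threading the
#' comparator states through time.
#'
#' @param filtered a `filtered_trace` from [moving_average_filter()].
#' @param th a `threshold_set`.
#' @return A data frame with one row per sample: `t_s`, `forward`,
#'   `left`, `right` (0/1 flags) and `message`.
#' @export
assess_trace <- function(filtered, th) {
  cmps <- build_comparators(th)
  n <- nrow(filtered)
  fwd <- integer(n); lft <- integer(n); rgt <- integer(n)
  msg <- character(n)
  for (k in seq_len(n)) {
    res <- assess(filtered$A_x[k], filtered$A_y[k], cmps, S_y = th$S_y)
    cmps <- res$comparators
    fwd[k] <- as.integer("forward" %in% res$state$flags)
    lft[k] <- as.integer("left" %in% res$state$flags)
    rgt[k] <- as.integer("right" %in% res$state$flags)
    msg[k] <- res$state$message
  }
  data.frame(t_s = filtered$t_s, forward = fwd, left = lft, right = rgt,
             message = msg, stringsAsFactors = FALSE)
}

#' Emit throttled reminder events from a posture stream
#'
#' Walks a time-ordered stream of posture assessments and produces
#' reminder events: one when the flag set becomes non-empty or changes,
#' and repeats while poor posture persists, at most once per throttle
#' interval. The interval is `T0 / warning_time` seconds, so a higher
#' `warning_time` means more frequent reminders. No events are emitted
#' while the flags are empty.
#'
#' @param assessments data frame from [assess_trace()] (columns `t_s`,
#'   `forward`, `left`, `right`).
#' @param warning_time positive integer reminder-frequency setting;
#'   default 1.
#' @param T0 base throttle period in seconds; default 10.
#' @return Data frame of events: `t_s`, `flags` (list column), `message`.
#' @export
emit_reminders <- function(assessments, warning_time = 1, T0 = 10) {
  if (length(warning_time) != 1L || !is.finite(warning_time) ||
      warning_time < 1 || warning_time != round(warning_time)) {
    stop("warning_time must be a positive integer", call. = FALSE)
  }
  if (is.unsorted(assessments$t_s, strictly = TRUE)) {
    stop("assessment stream must be strictly time-ordered", call. = FALSE)
  }
  interval <- T0 / warning_time
  ev_t <- numeric(0); ev_flags <- list(); ev_msg <- character(0)
  last_t <- -Inf
  last_flags <- character(0)
  for (k in seq_len(nrow(assessments))) {
    flags <- c("forward", "left", "right")[
      c(assessments$forward[k], assessments$left[k],
        assessments$right[k]) == 1]
    if (length(flags) == 0L) {
      last_flags <- character(0)
      last_t <- -Inf
      next
    }
    changed <- !identical(flags, last_flags)
    if (changed || assessments$t_s[k] - last_t >= interval) {
      st <- posture_state(flags)
      ev_t <- c(ev_t, assessments$t_s[k])
      ev_flags <- c(ev_flags, list(st$flags))
      ev_msg <- c(ev_msg, st$message)
      last_t <- assessments$t_s[k]
      last_flags <- flags
    }
  }
  out <- data.frame(t_s = ev_t, message = ev_msg, stringsAsFactors = FALSE)
  out$flags <- ev_flags
  out[, c("t_s", "flags", "message")]
}

#' Write reminder events as JSON lines
#'
#' One JSON object per line:
#' `{"t": <seconds>, "type": "reminder", "flags": [...], "message": "..."}`.
#'
#' @param events data frame from [emit_reminders()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_events_jsonl <- function(events, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (k in seq_len(nrow(events))) {
    obj <- list(t = events$t_s[k], type = "reminder",
                flags = as.list(events$flags[[k]]),
                message = events$message[k])
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
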