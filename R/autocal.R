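#' Auto-calibrate standard values from keypoints and filtered signal
#'
#' The primary calibration mechanism: the wearer's standard values are
#' sampled from the filtered accelerometer signal at the instants their
#' keypoint geometry certifies correct posture. Calibration runs in two
#' phases, in order. First the side profile: once the head-neck line has
#' been vertical (within `tol_deg`) for `hold_frames` consecutive frames,
#' the filtered spine-axis value `A_x` at that instant becomes `S_x`.
#' Then the frontal profile: once the shoulder line has been horizontal
#' for `hold_frames` consecutive frames, the filtered lateral value `A_y`
#' at that instant becomes `S_y`. The debounce over `hold_frames` frames
#' prevents calibrating on a single transient frame; the standard is the
#' filtered value at the qualifying instant, not an average over the hold
#' window.
#'
#' If the streams end before a phase completes, the corresponding
#' standard is returned as `NA` and the status reports the partial
#' completion; this is a status, not an error, so a caller can retry with
#' a longer recording.
#'
#' @param keypoints a `keypoint_frames` data frame (see
#'   [read_keypoints()]), time-aligned with `filtered`.
#' @param filtered a `filtered_trace` from [moving_average_filter()].
#' @param hold_frames consecutive qualifying frames required before
#'   sampling; default 5.
#' @param tol_deg angular tolerance for the geometry checks, degrees;
#'   default 2.
#' @return List of class `calibration_result`: `S_x`, `S_y` (G, `NA` if
#'   not calibrated), `t_S_x`, `t_S_y` (sampling instants), and `status`
#'   (`"complete"`, `"S_y not calibrated"`, or `"S_x not calibrated"`).
#' @export
auto_calibrate <- function(keypoints, filtered, hold_frames = 5,
                           tol_deg = 2.0) {
  if (hold_frames < 1) stop("hold_frames must be >= 1", call. = FALSE)
  S_x <- NA_real_; S_y <- NA_real_
  t_S_x <- NA_real_; t_S_y <- NA_real_
  phase <- "side"   # side profile (vertical head-neck) first, then frontal
  run <- 0L
  for (k in seq_len(nrow(keypoints))) {
    t <- keypoints$t_s[k]
    ok <- if (phase == "side") {
      is_vertical(c(keypoints$head_u[k], keypoints$head_v[k]),
                  c(keypoints$neck_u[k], keypoints$neck_v[k]), tol_deg)
    } else {
      is_horizontal(c(keypoints$lsh_u[k], keypoints$lsh_v[k]),
                    c(keypoints$rsh_u[k], keypoints$rsh_v[k]), tol_deg)
    }
    run <- if (ok) run + 1L else 0L
    if (run >= hold_frames) {
      val <- filtered_at(filtered, t)
      if (phase == "side") {
        S_x <- val$A_x; t_S_x <- t
        phase <- "frontal"; run <- 0L
      } else {
        S_y <- val$A_y; t_S_y <- t
        break
      }
    }
  }
  status <- if (!is.na(S_x) && !is.na(S_y)) "complete"
  else if (!is.na(S_x)) "S_y not calibrated"
  else "S_x not calibrated"
  structure(list(S_x = S_x, S_y = S_y, t_S_x = t_S_x, t_S_y = t_S_y,
                 status = status),
            class = "calibration_result")
}

# filtered value in effect at time t: the latest sample with t_s <= t
# (or the first sample when t precedes the trace)
filtered_at <- function(filtered, t) {
  idx <- findInterval(t, filtered$t_s)
  idx <- max(idx, 1L)
  list(A_x = filtered$A_x[idx], A_y = filtered$A_y[idx])
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("Auto-calibration:", x$status, "\n")
  if (!is.na(x$S_x)) {
    cat(sprintf("  S_x = %.5f G (at t = %.1f s)\n", x$S_x, x$t_S_x))
  }
  if (!is.na(x$S_y)) {
    cat(sprintf("  S_y = %.5f G (at t = %.1f s)\n", x$S_y, x$t_S_y))
  }
  invisible(x)
}
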