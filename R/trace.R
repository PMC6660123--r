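#' Construct an accelerometer trace
#'
#' An accelerometer trace holds timestamped raw triaxial gravitational
#' acceleration readings, in units of G (multiples of standard gravity).
#' The x axis runs along the spine (reads ~1 G when the wearer is upright),
#' the y axis is lateral, and the z axis is anteroposterior; z is carried
#' through the pipeline but never used for posture assessment.
#'
#' @param t_s numeric vector of seconds since session start; strictly
#'   increasing.
#' @param ax_g,ay_g,az_g numeric vectors of per-axis readings in G.
#' @param full_scale sensor full-scale guard in G; readings with absolute
#'   value above it are rejected. Default 4 (a +/-4 G accelerometer range).
#' @return A data frame of class `accel_trace` with columns
#'   `t_s, ax_g, ay_g, az_g`.
#' @export
#' @examples
#' accel_trace(t_s = c(0, 0.1, 0.2), ax_g = c(1, 1, 0.99),
#'             ay_g = c(0, 0.01, 0), az_g = c(0, 0, 0))
accel_trace <- function(t_s, ax_g, ay_g, az_g = numeric(length(t_s)),
                        full_scale = 4) {
  n <- length(t_s)
  if (n == 0L) {
    stop("empty trace: at least one sample is required", call. = FALSE)
  }
  if (length(ax_g) != n || length(ay_g) != n || length(az_g) != n) {
    stop("t_s, ax_g, ay_g, az_g must have equal length", call. = FALSE)
  }
  if (anyNA(t_s) || any(diff(t_s) <= 0)) {
    stop("timestamps must be finite and strictly increasing", call. = FALSE)
  }
  for (axis in list(ax = ax_g, ay = ay_g, az = az_g)) {
    if (anyNA(axis) || any(abs(axis) > full_scale)) {
      stop(sprintf("readings must be finite and within +/-%g G full scale",
                   full_scale), call. = FALSE)
    }
  }
  out <- data.frame(t_s = as.numeric(t_s), ax_g = as.numeric(ax_g),
                    ay_g = as.numeric(ay_g), az_g = as.numeric(az_g))
  class(out) <- c("accel_trace", "data.frame")
  out
}

#' Read an accelerometer trace from CSV
#'
#' The trace CSV dialect has header `t_s,ax_g,ay_g,az_g`, one sample per
#' row, decimal points, UTF-8. `read_trace()` and [write_trace()] round-trip
#' losslessly.
#'
#' @param path path to a trace CSV file.
#' @param full_scale passed to [accel_trace()].
#' @return An `accel_trace`.
#' @export
read_trace <- function(path, full_scale = 4) {
  if (!file.exists(path)) stop("trace file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  required <- c("t_s", "ax_g", "ay_g")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop("trace CSV is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(raw) == 0L) stop("empty trace file: ", path, call. = FALSE)
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) & nzchar(raw[[col]]))
    bad <- c(bad, which(is.na(raw[[col]]) | !nzchar(raw[[col]])))
    if (length(bad) > 0L) {
      # +1 for the header line so the message points at the file line
      stop(sprintf("malformed value in column '%s' at line %d of %s",
                   col, min(bad) + 1L, path), call. = FALSE)
    }
    v
  }
  az <- if ("az_g" %in% names(raw)) num("az_g") else numeric(nrow(raw))
  accel_trace(num("t_s"), num("ax_g"), num("ay_g"), az,
              full_scale = full_scale)
}

#' Write an accelerometer trace to CSV
#'
#' @param trace an `accel_trace` (or data frame with the trace columns).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(all(c("t_s", "ax_g", "ay_g", "az_g") %in% names(trace)))
  utils::write.csv(
    data.frame(t_s = format_num(trace$t_s), ax_g = format_num(trace$ax_g),
               ay_g = format_num(trace$ay_g), az_g = format_num(trace$az_g)),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# full-precision, locale-independent numeric formatting for CSV output
format_num <- function(x) {
  formatC(x, digits = 17, format = "g", drop0trailing = TRUE)
}
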