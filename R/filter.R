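#' Moving-average filter for accelerometer traces
#'
#' Digitally filters the x- and y-axis signals of a trace with a trailing
#' moving average: element k of the output is the arithmetic mean of the
#' current raw reading and the previous `window - 1` readings. Before a
#' full window has accumulated, the mean of all samples seen so far is used
#' (`window_fill` reports how many samples actually contributed), so output
#' and input stay aligned sample for sample.
#'
#' The default window of 10 at a 10 Hz sampling rate averages one second
#' of signal, which suppresses the sample-to-sample jitter of a worn
#' accelerometer (most visibly the walking-induced oscillation on the
#' spine axis) while tracking genuine postural tilt.
#'
#' @param trace an [accel_trace()] (or data frame with columns
#'   `t_s, ax_g, ay_g`).
#' @param window positive integer window length in samples; default 10.
#' @return A data frame of class `filtered_trace` with columns `t_s`,
#'   `A_x`, `A_y` (filtered values, G) and `window_fill`.
#' @export
#' @examples
#' tr <- accel_trace(t_s = seq(0, 1.9, by = 0.1),
#'                   ax_g = rep(1, 20), ay_g = rep(0, 20))
#' moving_average_filter(tr)
moving_average_filter <- function(trace, window = 10) {
  if (is.null(trace) || nrow(trace) == 0L) {
    stop("empty input: nothing to filter", call. = FALSE)
  }
  if (any(diff(trace$t_s) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  window <- as.integer(window)
  if (is.na(window) || window < 1L) {
    stop("window must be a positive integer", call. = FALSE)
  }
  n <- nrow(trace)
  fill <- pmin(seq_len(n), window)
  out <- data.frame(
    t_s = trace$t_s,
    A_x = trailing_mean(trace$ax_g, window, fill),
    A_y = trailing_mean(trace$ay_g, window, fill),
    window_fill = fill)
  class(out) <- c("filtered_trace", "data.frame")
  out
}

# trailing windowed mean via cumulative sums; fill = samples in each window
trailing_mean <- function(x, window, fill) {
  cs <- cumsum(x)
  lagged <- c(rep(0, window), cs[seq_len(max(0L, length(x) - window))])
  (cs - lagged[seq_along(x)]) / fill
}
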