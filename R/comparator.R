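#' Hysteresis comparator
#'
#' A two-threshold binary decision element. A `triggers-above` comparator
#' sets its output to 1 when the input rises above the trigger threshold
#' `href` and back to 0 only when the input falls below the release
#' threshold `lref`; a `triggers-below` comparator mirrors this (trips when
#' the input falls below `href`, releases when it rises above `lref`).
#' Inputs inside the open band between the two thresholds leave the output
#' unchanged, which is what prevents chattering near a single cutoff.
#'
#' Polarity is derived from the threshold geometry: `href > lref` means the
#' comparator trips on high inputs (the leftward-tilt comparator, whose
#' trigger sits above its release), `href < lref` means it trips on low
#' inputs (the forward and rightward comparators, whose trigger thresholds
#' sit below their release thresholds).
#'
#' @param href trigger threshold, G.
#' @param lref release threshold, G; must differ from `href`.
#' @param out initial output, 0 (posture acceptable) or 1 (poor); default 0.
#' @return An object of class `hysteresis_comparator` with fields `out`,
#'   `polarity` (`"triggers-above"` or `"triggers-below"`), `href`, `lref`.
#' @export
#' @examples
#' cmp <- hysteresis_comparator(href = 0.02834, lref = 0.02441)
#' cmp <- comparator_step(cmp, 0.030)  # above href: trips
#' cmp$out
hysteresis_comparator <- function(href, lref, out = 0L) {
  if (!is.finite(href) || !is.finite(lref)) {
    stop("thresholds must be finite", call. = FALSE)
  }
  if (href == lref) {
    stop("degenerate band: href must differ from lref", call. = FALSE)
  }
  if (!out %in% c(0L, 1L)) stop("out must be 0 or 1", call. = FALSE)
  structure(list(
    out = as.integer(out),
    polarity = if (href > lref) "triggers-above" else "triggers-below",
    href = href, lref = lref),
    class = "hysteresis_comparator")
}

#' Advance a hysteresis comparator by one input value
#'
#' @param state a [hysteresis_comparator()].
#' @param value the input, G (the filtered axis reading fed to this
#'   comparator).
#' @return The updated comparator.
#' @export
comparator_step <- function(state, value) {
  if (!is.finite(value)) stop("comparator input must be finite", call. = FALSE)
  if (state$polarity == "triggers-above") {
    if (value > state$href) state$out <- 1L
    else if (value < state$lref) state$out <- 0L
  } else {
    if (value < state$href) state$out <- 1L
    else if (value > state$lref) state$out <- 0L
  }
  state
}

#' Build the three posture comparators from a threshold set
#'
#' The forward comparator watches the filtered spine-axis value `A_x` and
#' trips when it drops below `Href_x` (the wearer leaning forward lowers
#' the gravity component along the spine). The left comparator watches the
#' lateral value `A_y` and trips when it rises above `Href_yl`; the right
#' comparator trips when `A_y` drops below `Href_yr`. All start at
#' `out = 0`: posture is presumed correct at session start, consistent
#' with calibration immediately preceding assessment.
#'
#' @param th a `threshold_set` (see [build_threshold_set()]).
#' @return Named list of three `hysteresis_comparator`s:
#'   `forward`, `left`, `right`.
#' @export
build_comparators <- function(th) {
  validate_threshold_set(th)
  list(
    forward = hysteresis_comparator(th$Href_x, th$Lref_x),
    left    = hysteresis_comparator(th$Href_yl, th$Lref_yl),
    right   = hysteresis_comparator(th$Href_yr, th$Lref_yr))
}

#' @export
print.hysteresis_comparator <- function(x, ...) {
  cat(sprintf("hysteresis comparator (%s): out = %d, href = %.5f, lref = %.5f\n",
              x$polarity, x$out, x$href, x$lref))
  invisible(x)
}
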