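#' Default comparator offsets
#'
#' The offsets between a wearer's standard values and the comparator
#' thresholds, in G. The trigger offsets (`dH_fwd`, `dH_lat`) are the
#' minimum poor-posture tilt changes observed across three
#' orthopedist-assessed users of different shoulder widths; the release
#' offsets (`dL_fwd`, `dL_lat`) are slightly smaller values selected after
#' repeated evaluation so the comparators release before reminders become
#' erratic. They define the hysteresis bands:
#' \itemize{
#'   \item forward: `Href_x = S_x - dH_fwd`, `Lref_x = S_x - dL_fwd`
#'   \item left: `Href_yl = S_y + dH_lat`, `Lref_yl = S_y + dL_lat`
#'   \item right: `Href_yr = S_y - dH_lat`, `Lref_yr = S_y - dL_lat`
#' }
#'
#' @return Named list with entries `dH_fwd`, `dL_fwd`, `dH_lat`, `dL_lat`
#'   (all in G).
#' @export
default_offsets <- function() {
  list(dH_fwd = 0.01159, dL_fwd = 0.00854,
       dH_lat = 0.02834, dL_lat = 0.02441)
}

#' Read orthopedist-labeled tilt measurements from CSV
#'
#' Each row records, for one user and one tilt direction, the user's
#' calibrated standard value and the filtered reading at the moment an
#' orthopedist declared the posture poor. Header:
#' `user,direction,standard_g,measured_g` with direction one of
#' `forward`, `left`, `right`.
#'
#' @param path CSV path.
#' @return Data frame with columns `user`, `direction`, `standard_g`,
#'   `measured_g`, and the derived `change_g = |standard_g - measured_g|`.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) {
    stop("measurements file not found: ", path, call. = FALSE)
  }
  m <- utils::read.csv(path, strip.white = TRUE)
  required <- c("user", "direction", "standard_g", "measured_g")
  missing <- setdiff(required, names(m))
  if (length(missing) > 0L) {
    stop("measurements CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(m$direction), c("forward", "left", "right"))
  if (length(bad) > 0L) {
    stop("unknown direction value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  m$change_g <- abs(m$standard_g - m$measured_g)
  m
}

#' Derive comparator trigger offsets from labeled measurements
#'
#' For each labeled measurement the tilt change is
#' `|standard - measured|`. The forward trigger offset is the minimum
#' change over all forward measurements; the lateral trigger offset is the
#' minimum over all left and right measurements pooled. Taking the minimum
#' makes the assessment deliberately strict: even the least pronounced tilt
#' any assessed user needed to reach a clinician-declared poor posture will
#' trip the comparator.
#'
#' @param measurements data frame as returned by [read_measurements()]
#'   (columns `direction`, `standard_g`, `measured_g`).
#' @return List with `forward_offset` and `lateral_offset`, in G.
#' @export
#' @examples
#' path <- system.file("extdata", "orthopedist_measurements.csv",
#'                     package = "posturekit")
#' derive_offsets(read_measurements(path))
derive_offsets <- function(measurements) {
  change <- abs(measurements$standard_g - measurements$measured_g)
  fwd <- change[measurements$direction == "forward"]
  lat <- change[measurements$direction %in% c("left", "right")]
  if (length(fwd) == 0L || length(lat) == 0L) {
    stop("need at least one forward and one lateral (left/right) measurement",
         call. = FALSE)
  }
  list(forward_offset = min(fwd), lateral_offset = min(lat))
}

#' Build a threshold set from calibrated standard values
#'
#' Computes the six comparator thresholds from the wearer's standard
#' values `S_x` (forward/back axis, ~1 G upright) and `S_y` (lateral
#' axis), using the default offsets (see [default_offsets()]) or an
#' override. The four adjustment sliders `a, b, c, d` are initialized to
#' their central value 150 (identity). The calibration-time `S_x`, `S_y`
#' are stored as the base for slider adjustment, so repeated slider
#' applications never compound.
#'
#' @param S_x forward standard value, G.
#' @param S_y lateral standard value, G.
#' @param offsets optional list overriding any of `dH_fwd`, `dL_fwd`,
#'   `dH_lat`, `dL_lat`.
#' @return An object of class `threshold_set`: a list with fields `S_x`,
#'   `S_y`, `Href_x`, `Lref_x`, `Href_yl`, `Lref_yl`, `Href_yr`,
#'   `Lref_yr`, sliders `a, b, c, d`, plus the stored `offsets` and base
#'   standards.
#' @export
#' @examples
#' build_threshold_set(S_x = 1.0, S_y = 0.0)
build_threshold_set <- function(S_x, S_y, offsets = NULL) {
  if (!is.finite(S_x) || !is.finite(S_y)) {
    stop("S_x and S_y must be finite", call. = FALSE)
  }
  off <- utils::modifyList(default_offsets(), as.list(offsets %||% list()))
  if (off$dH_fwd <= off$dL_fwd || off$dH_lat <= off$dL_lat) {
    stop("trigger offsets must exceed release offsets (dH > dL)",
         call. = FALSE)
  }
  th <- structure(list(
    S_x = S_x, S_y = S_y,
    Href_x  = S_x - off$dH_fwd, Lref_x  = S_x - off$dL_fwd,
    Href_yl = S_y + off$dH_lat, Lref_yl = S_y + off$dL_lat,
    Href_yr = S_y - off$dH_lat, Lref_yr = S_y - off$dL_lat,
    a = 150L, b = 150L, c = 150L, d = 150L,
    offsets = off, base_S_x = S_x, base_S_y = S_y),
    class = "threshold_set")
  validate_threshold_set(th)
  th
}

validate_threshold_set <- function(th) {
  ok <- th$Href_x < th$Lref_x && th$Lref_x < th$S_x &&
    th$Lref_yl < th$Href_yl && th$S_y < th$Lref_yl &&
    th$Href_yr < th$Lref_yr && th$Lref_yr < th$S_y
  if (!ok) {
    stop("threshold set violates band ordering invariants", call. = FALSE)
  }
  invisible(th)
}

#' Apply manual adjustment sliders to a threshold set
#'
#' The four sliders rescale the calibrated parameters relative to a
#' central identity value of 150, each over the range 1-300:
#' \itemize{
#'   \item `a` scales the forward standard value: `S_x = base_S_x * a/150`
#'   \item `b` scales the forward threshold offsets:
#'     `Href_x = S_x - dH_fwd * b/150`, `Lref_x = S_x - dL_fwd * b/150`
#'   \item `c` scales the lateral standard value: `S_y = base_S_y * c/150`
#'   \item `d` scales the lateral threshold offsets analogously
#' }
#' The sliders act independently and are always applied to the stored
#' calibration-time base values, never to previously adjusted values, so
#' applying the same slider twice equals applying it once and slider
#' position maps deterministically onto the resulting state.
#'
#' @param base a `threshold_set`.
#' @param a,b,c,d integer slider positions in `[1, 300]`; default: keep
#'   the base set's current positions.
#' @return A new `threshold_set` with the adjustments applied.
#' @export
#' @examples
#' th <- build_threshold_set(1.0, 0.0)
#' apply_sliders(th, b = 300)  # doubled forward band
apply_sliders <- function(base, a = base$a, b = base$b, c = base$c,
                          d = base$d) {
  # argument `c` shadows base::c here, so validate one by one
  for (s in list(a, b, c, d)) {
    if (length(s) != 1L || !is.finite(s) || s != round(s) || s < 1 ||
        s > 300) {
      stop("sliders must be integers in [1, 300]", call. = FALSE)
    }
  }
  off <- base$offsets
  S_x <- base$base_S_x * a / 150
  S_y <- base$base_S_y * c / 150
  th <- structure(list(
    S_x = S_x, S_y = S_y,
    Href_x  = S_x - off$dH_fwd * b / 150,
    Lref_x  = S_x - off$dL_fwd * b / 150,
    Href_yl = S_y + off$dH_lat * d / 150,
    Lref_yl = S_y + off$dL_lat * d / 150,
    Href_yr = S_y - off$dH_lat * d / 150,
    Lref_yr = S_y - off$dL_lat * d / 150,
    a = as.integer(a), b = as.integer(b), c = as.integer(c),
    d = as.integer(d),
    offsets = off, base_S_x = base$base_S_x, base_S_y = base$base_S_y),
    class = "threshold_set")
  validate_threshold_set(th)
  th
}

#' @export
print.threshold_set <- function(x, ...) {
  cat("Posture threshold set (G)\n")
  cat(sprintf("  forward: S_x = %.5f  band [Href_x = %.5f, Lref_x = %.5f]\n",
              x$S_x, x$Href_x, x$Lref_x))
  cat(sprintf("  left:    S_y = %.5f  band [Lref_yl = %.5f, Href_yl = %.5f]\n",
              x$S_y, x$Lref_yl, x$Href_yl))
  cat(sprintf("  right:               band [Href_yr = %.5f, Lref_yr = %.5f]\n",
              x$Href_yr, x$Lref_yr))
  cat(sprintf("  sliders: a = %d, b = %d, c = %d, d = %d\n",
              x$a, x$b, x$c, x$d))
  invisible(x)
}

#' Write / read a threshold set as JSON
#'
#' The JSON mirrors the threshold set field names
#' (`S_x, S_y, Href_x, Lref_x, Href_yl, Lref_yl, Href_yr, Lref_yr,
#' a, b, c, d`), plus the stored offsets and base standards so slider
#' semantics survive the round trip.
#'
#' @param th a `threshold_set`.
#' @param path JSON file path.
#' @return `write_thresholds()`: `path` invisibly; `read_thresholds()`:
#'   a `threshold_set`.
#' @export
write_thresholds <- function(th, path) {
  jsonlite::write_json(unclass(th), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  if (!file.exists(path)) {
    stop("thresholds file not found: ", path, call. = FALSE)
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- build_threshold_set(
    S_x = raw$base_S_x %||% raw$S_x,
    S_y = raw$base_S_y %||% raw$S_y,
    offsets = raw$offsets)
  apply_sliders(base, a = raw$a %||% 150, b = raw$b %||% 150,
                c = raw$c %||% 150, d = raw$d %||% 150)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
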