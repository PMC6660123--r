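#' Project gravity onto the necklace's accelerometer axes
#'
#' Given the wearer's pitch (forward-positive) and roll (left-positive)
#' in degrees, returns the noiseless accelerometer reading in G. The
#' necklace is worn at the back of the neck with the accelerometer's
#' x axis along the spine, y axis lateral, and z axis anteroposterior, so
#' an upright wearer reads `(ax, ay, az) = (1, 0, 0)`:
#' \deqn{a_x = \cos(pitch)\cos(roll),\quad a_y = \sin(roll),\quad
#'       a_z = -\sin(pitch)\cos(roll)}
#' Pitching forward lowers `ax`; rolling leftward raises `ay`; rolling
#' rightward (negative roll) lowers `ay`. The projection conserves unit
#' gravity: \eqn{a_x^2 + a_y^2 + a_z^2 = 1}.
#'
#' This axis convention is an assumption of the simulator, fixed from the
#' observed signal directions of a worn device (upright spine axis near
#' 1 G, leftward roll raising the lateral reading).
#'
#' @param pitch,roll angles in degrees, each within `[-90, 90]`;
#'   vectorized.
#' @return Data frame with columns `ax`, `ay`, `az` (G).
#' @export
#' @examples
#' gravity_projection(0, 0)    # upright: ax = 1
#' gravity_projection(60, 0)   # deep forward tilt: ax = 0.5
gravity_projection <- function(pitch, roll) {
  if (any(!is.finite(pitch)) || any(!is.finite(roll)) ||
      any(abs(pitch) > 90) || any(abs(roll) > 90)) {
    stop("pitch and roll must be finite and within [-90, 90] degrees",
         call. = FALSE)
  }
  p <- pitch * pi / 180
  r <- roll * pi / 180
  data.frame(ax = cos(p) * cos(r), ay = sin(r), az = -sin(p) * cos(r))
}

#' Scripted wearer maneuver
#'
#' A maneuver is an ordered list of segments, each holding or linearly
#' ramping the wearer's pitch and roll over a duration. The simulator
#' turns a maneuver into an accelerometer trace (and matching keypoint
#' stream) so the rest of the pipeline can run without hardware.
#'
#' Noise defaults emulate a stationary wearer: additive Gaussian noise of
#' 0.005 G per axis. With `walking = TRUE` a sinusoidal perturbation of
#' amplitude `walking_amp` at `walking_freq` is added to the spine-axis
#' signal, mimicking the step-synchronous oscillation that dominates the
#' raw x-axis signal when walking. Constant `mounting_pitch` and
#' `mounting_roll` offsets model how the necklace sits on an individual
#' wearer: they tilt the sensor, not the body, so a geometrically correct
#' posture still yields wearer-specific standard values (an upright
#' spine-axis reading below 1 G, a non-zero upright lateral reading).
#'
#' @param segments data frame (or list coercible to one) with columns
#'   `duration` (s, positive), `target_pitch`, `target_roll` (degrees,
#'   within `[-90, 90]`), `transition` (`"hold"` or `"linear"`).
#' @param sample_rate sampling rate, Hz; default 10.
#' @param noise_sigma Gaussian noise standard deviation, G; default
#'   0.005.
#' @param walking logical; add walking perturbation to ax. Default FALSE.
#' @param walking_amp walking perturbation amplitude, G; default 0.05.
#' @param walking_freq walking perturbation frequency, Hz; default 2.
#' @param mounting_pitch,mounting_roll constant wearer mounting offsets,
#'   degrees; default 0. Applied to the sensor orientation only, never to
#'   the keypoint geometry.
#' @param seed integer RNG seed; default 1.
#' @return An object of class `maneuver_spec`.
#' @export
#' @examples
#' maneuver_spec(data.frame(
#'   duration = c(3, 2, 5), target_pitch = c(0, 30, 30),
#'   target_roll = 0, transition = c("hold", "linear", "hold")))
maneuver_spec <- function(segments, sample_rate = 10, noise_sigma = 0.005,
                          walking = FALSE, walking_amp = 0.05,
                          walking_freq = 2.0, mounting_pitch = 0,
                          mounting_roll = 0, seed = 1L) {
  segments <- as.data.frame(segments)
  required <- c("duration", "target_pitch", "target_roll", "transition")
  missing <- setdiff(required, names(segments))
  if (length(missing) > 0L) {
    stop("maneuver segments need column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(segments$duration <= 0)) {
    stop("segment durations must be positive", call. = FALSE)
  }
  if (any(abs(segments$target_pitch) > 90) ||
      any(abs(segments$target_roll) > 90)) {
    stop("target angles must be within [-90, 90] degrees", call. = FALSE)
  }
  if (!all(segments$transition %in% c("hold", "linear"))) {
    stop("transition must be 'hold' or 'linear'", call. = FALSE)
  }
  structure(list(segments = segments, sample_rate = sample_rate,
                 noise_sigma = noise_sigma, walking = walking,
                 walking_amp = walking_amp, walking_freq = walking_freq,
                 mounting_pitch = mounting_pitch,
                 mounting_roll = mounting_roll, seed = as.integer(seed)),
            class = "maneuver_spec")
}

# per-sample pitch/roll trajectory implied by the segment script
maneuver_angles <- function(spec) {
  dt <- 1 / spec$sample_rate
  total <- sum(spec$segments$duration)
  t <- seq(0, total - dt, by = dt)
  pitch <- numeric(length(t)); roll <- numeric(length(t))
  seg_start <- cumsum(c(0, spec$segments$duration))
  prev_pitch <- 0; prev_roll <- 0
  for (s in seq_len(nrow(spec$segments))) {
    seg <- spec$segments[s, ]
    in_seg <- t >= seg_start[s] & t < seg_start[s + 1]
    if (seg$transition == "hold") {
      pitch[in_seg] <- seg$target_pitch
      roll[in_seg] <- seg$target_roll
    } else {
      frac <- (t[in_seg] - seg_start[s]) / seg$duration
      pitch[in_seg] <- prev_pitch + frac * (seg$target_pitch - prev_pitch)
      roll[in_seg] <- prev_roll + frac * (seg$target_roll - prev_roll)
    }
    prev_pitch <- seg$target_pitch
    prev_roll <- seg$target_roll
  }
  data.frame(t_s = t, pitch = pitch, roll = roll)
}

#' Simulate an accelerometer trace from a maneuver
#'
#' Interpolates the maneuver's pitch/roll trajectory at the sampling
#' rate, projects gravity onto the sensor axes, and adds the configured
#' noise. Deterministic given the spec's seed. Ground truth records the
#' per-sample angles and the true posture flags under an angle
#' criterion: pitch above `flag_pitch_deg` is a forward tilt, roll
#' beyond `flag_roll_deg` (relative to the mounting roll) a left or
#' right tilt.
#'
#' @param spec a [maneuver_spec()].
#' @param flag_pitch_deg,flag_roll_deg ground-truth angle criteria,
#'   degrees; defaults 5.
#' @return List with `trace` (an [accel_trace()]) and `truth` (data
#'   frame `t_s, pitch_deg, roll_deg, flag_forward, flag_left,
#'   flag_right`).
#' @export
simulate_trace <- function(spec, flag_pitch_deg = 5, flag_roll_deg = 5) {
  ang <- maneuver_angles(spec)
  g <- gravity_projection(ang$pitch + spec$mounting_pitch,
                          ang$roll + spec$mounting_roll)
  n <- nrow(ang)
  noise <- with_local_seed(spec$seed, {
    matrix(stats::rnorm(3 * n, sd = spec$noise_sigma), ncol = 3)
  })
  ax <- g$ax + noise[, 1]
  ay <- g$ay + noise[, 2]
  az <- g$az + noise[, 3]
  if (spec$walking) {
    ax <- ax + spec$walking_amp *
      sin(2 * pi * spec$walking_freq * ang$t_s)
  }
  trace <- accel_trace(ang$t_s, ax, ay, az)
  truth <- data.frame(
    t_s = ang$t_s, pitch_deg = ang$pitch, roll_deg = ang$roll,
    flag_forward = as.integer(ang$pitch > flag_pitch_deg),
    flag_left = as.integer(ang$roll > flag_roll_deg),
    flag_right = as.integer(ang$roll < -flag_roll_deg))
  list(trace = trace, truth = truth)
}

# evaluate expr under a temporary RNG state seeded with `seed`
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Simulate a skeletal keypoint stream from a maneuver
#'
#' Emits one keypoint frame per accelerometer sample, time-aligned with
#' the simulated trace. The head-neck segment is tilted from vertical by
#' the current pitch (as seen in the side profile), and the shoulder
#' line is tilted from horizontal by the current roll (frontal profile).
#' The camera is assumed to capture whichever profile the calibration
#' phase needs, so both geometric conditions are encoded in every frame.
#'
#' @param spec a [maneuver_spec()].
#' @param neck_height neck keypoint height above ground, world units;
#'   default 1.4.
#' @param head_length head-neck segment length; default 0.25.
#' @param shoulder_halfwidth half the shoulder span; default 0.2.
#' @param jitter_sd Gaussian keypoint jitter, world units; default 0
#'   (noiseless geometry).
#' @return A `keypoint_frames` data frame.
#' @export
simulate_keypoints <- function(spec, neck_height = 1.4, head_length = 0.25,
                               shoulder_halfwidth = 0.2, jitter_sd = 0) {
  if (neck_height <= 0 || head_length <= 0 || shoulder_halfwidth <= 0) {
    stop("body segment lengths must be positive", call. = FALSE)
  }
  ang <- maneuver_angles(spec)
  p <- ang$pitch * pi / 180
  r <- ang$roll * pi / 180
  kp <- data.frame(
    t_s = ang$t_s,
    head_u = head_length * sin(p),
    head_v = neck_height + head_length * cos(p),
    neck_u = 0,
    neck_v = neck_height,
    lsh_u = -shoulder_halfwidth * cos(r),
    lsh_v = neck_height - 0.05 + shoulder_halfwidth * sin(r),
    rsh_u = shoulder_halfwidth * cos(r),
    rsh_v = neck_height - 0.05 - shoulder_halfwidth * sin(r))
  if (jitter_sd > 0) {
    n <- nrow(kp)
    jit <- with_local_seed(spec$seed + 1L, {
      matrix(stats::rnorm(8 * n, sd = jitter_sd), ncol = 8)
    })
    kp[, -1] <- kp[, -1] + jit
  }
  class(kp) <- c("keypoint_frames", "data.frame")
  kp
}

#' Read a maneuver spec from YAML or JSON
#'
#' The file holds the [maneuver_spec()] fields; `segments` is a list of
#' mappings with `duration`, `target_pitch`, `target_roll`,
#' `transition`.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @param seed optional seed overriding the file's.
#' @return A `maneuver_spec`.
#' @export
read_maneuver <- function(path, seed = NULL) {
  if (!file.exists(path)) {
    stop("maneuver file not found: ", path, call. = FALSE)
  }
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  segments <- if (is.data.frame(raw$segments)) raw$segments else
    do.call(rbind, lapply(raw$segments, as.data.frame))
  args <- raw[setdiff(names(raw), "segments")]
  if (!is.null(seed)) args$seed <- seed
  do.call(maneuver_spec, c(list(segments = segments), args))
}

#' Write simulator ground truth as CSV
#'
#' Companion CSV with header
#' `t_s,pitch_deg,roll_deg,flag_forward,flag_left,flag_right`.
#'
#' @param truth ground-truth data frame from [simulate_trace()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
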