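# Brute-force oracles and fixture builders shared across tests.

# trailing windowed mean recomputed explicitly per index
oracle_moving_average <- function(x, window) {
  vapply(seq_along(x), function(k) {
    mean(x[max(1, k - window + 1):k])
  }, numeric(1))
}

# two-threshold hysteresis replay, written independently of the engine:
# keeps an explicit binary state and applies the trip/release rules
oracle_hysteresis <- function(values, href, lref, out0 = 0L) {
  out <- integer(length(values))
  state <- out0
  trips_high <- href > lref
  for (k in seq_along(values)) {
    v <- values[k]
    if (trips_high) {
      if (v > href) state <- 1L else if (v < lref) state <- 0L
    } else {
      if (v < href) state <- 1L else if (v > lref) state <- 0L
    }
    out[k] <- state
  }
  out
}

# reminder scheduler replay: emits at flag-set changes and then at most
# once per interval while the set persists
oracle_reminders <- function(t, flag_sets, interval) {
  emit <- logical(length(t))
  last_t <- -Inf
  last <- character(0)
  for (k in seq_along(t)) {
    fl <- flag_sets[[k]]
    if (length(fl) == 0) {
      last <- character(0)
      last_t <- -Inf
      next
    }
    if (!identical(fl, last) || t[k] - last_t >= interval) {
      emit[k] <- TRUE
      last_t <- t[k]
      last <- fl
    }
  }
  emit
}

random_trace <- function(n, seed, dt = 0.1, sd = 0.05) {
  set.seed(seed)
  accel_trace(t_s = seq(0, by = dt, length.out = n),
              ax_g = 1 + rnorm(n, sd = sd),
              ay_g = rnorm(n, sd = sd),
              az_g = rnorm(n, sd = sd))
}

# a calibrate -> tilt forward -> straighten maneuver used by several tests
tilt_session_spec <- function(seed = 1, pitch = 30, noise_sigma = 0.005,
                              mounting_pitch = 0, mounting_roll = 0) {
  maneuver_spec(
    data.frame(duration = c(5, 3, 10, 3, 5),
               target_pitch = c(0, pitch, pitch, 0, 0),
               target_roll = 0,
               transition = c("hold", "linear", "hold", "linear", "hold")),
    noise_sigma = noise_sigma, mounting_pitch = mounting_pitch,
    mounting_roll = mounting_roll, seed = seed)
}

measurements_fixture <- function() {
  read_measurements(system.file("extdata", "orthopedist_measurements.csv",
                                package = "posturekit"))
}
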