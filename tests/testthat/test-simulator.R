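test_that("gravity projection honors the mounting convention", {
  expect_equal(gravity_projection(0, 0), data.frame(ax = 1, ay = 0, az = 0))
  expect_equal(gravity_projection(60, 0)$ax, 0.5)
  g <- gravity_projection(0, 90)
  expect_equal(g$ay, 1)
  expect_equal(g$ax, 0, tolerance = 1e-15)
  # forward pitch lowers ax; leftward roll raises ay; rightward lowers it
  expect_lt(gravity_projection(20, 0)$ax, 1)
  expect_gt(gravity_projection(0, 15)$ay, 0)
  expect_lt(gravity_projection(0, -15)$ay, 0)
  expect_error(gravity_projection(91, 0), "\\[-90, 90\\]")
})

test_that("noiseless projections conserve unit gravity", {
  set.seed(61)
  pitch <- runif(200, -90, 90)
  roll <- runif(200, -90, 90)
  g <- gravity_projection(pitch, roll)
  expect_equal(g$ax^2 + g$ay^2 + g$az^2, rep(1, 200), tolerance = 1e-12)
})

test_that("a noiseless upright hold reads exactly 1 G on the spine axis", {
  spec <- maneuver_spec(data.frame(duration = 3, target_pitch = 0,
                                   target_roll = 0, transition = "hold"),
                        noise_sigma = 0)
  sim <- simulate_trace(spec)
  expect_equal(sim$trace$ax_g, rep(1, 30))
  expect_equal(sim$trace$ay_g, rep(0, 30))
  expect_equal(diff(sim$trace$t_s), rep(0.1, 29))
})

test_that("a forward ramp descends toward the projected cosine", {
  # ramp to 43.1 degrees: cos(43.1 deg) ~ 0.730
  spec <- maneuver_spec(data.frame(
    duration = c(2, 5, 3), target_pitch = c(0, 43.1, 43.1),
    target_roll = 0, transition = c("hold", "linear", "hold")),
    noise_sigma = 0)
  sim <- simulate_trace(spec)
  expect_equal(sim$trace$ax_g[nrow(sim$trace)], cos(43.1 * pi / 180))
  expect_equal(round(cos(43.1 * pi / 180), 2), 0.73)
  # descent is monotone during the ramp
  ramp <- sim$trace$ax_g[21:70]
  expect_true(all(diff(ramp) < 0))
})

test_that("equal seeds reproduce traces exactly; different seeds differ", {
  spec <- tilt_session_spec(seed = 77)
  a <- simulate_trace(spec)
  b <- simulate_trace(spec)
  expect_identical(a$trace, b$trace)
  c_ <- simulate_trace(tilt_session_spec(seed = 78))
  expect_false(identical(a$trace$ax_g, c_$trace$ax_g))
})

test_that("ground truth aligns with the trace and the angle criterion", {
  spec <- tilt_session_spec(seed = 5, pitch = 30)
  sim <- simulate_trace(spec, flag_pitch_deg = 5)
  expect_equal(nrow(sim$truth), nrow(sim$trace))
  expect_equal(sim$truth$flag_forward, as.integer(sim$truth$pitch_deg > 5))
  expect_true(any(sim$truth$flag_forward == 1))
  expect_equal(sum(sim$truth$flag_left), 0)
})

test_that("keypoint streams encode the scripted angles", {
  spec <- maneuver_spec(data.frame(duration = 2, target_pitch = 0,
                                   target_roll = 0, transition = "hold"))
  kp <- simulate_keypoints(spec)
  for (k in seq_len(nrow(kp))) {
    expect_true(is_vertical(c(kp$head_u[k], kp$head_v[k]),
                            c(kp$neck_u[k], kp$neck_v[k])))
    expect_true(is_horizontal(c(kp$lsh_u[k], kp$lsh_v[k]),
                              c(kp$rsh_u[k], kp$rsh_v[k])))
  }
  spec10 <- maneuver_spec(data.frame(duration = 2, target_pitch = 5,
                                     target_roll = 10, transition = "hold"))
  kp10 <- simulate_keypoints(spec10)
  expect_false(is_vertical(c(kp10$head_u[1], kp10$head_v[1]),
                           c(kp10$neck_u[1], kp10$neck_v[1]), tol_deg = 2))
  expect_false(is_horizontal(c(kp10$lsh_u[1], kp10$lsh_v[1]),
                             c(kp10$rsh_u[1], kp10$rsh_v[1]), tol_deg = 2))
})

test_that("filtering shrinks the walking-noise fluctuation on the spine axis", {
  spec <- maneuver_spec(data.frame(duration = 30, target_pitch = 0,
                                   target_roll = 0, transition = "hold"),
                        walking = TRUE, seed = 13)
  sim <- simulate_trace(spec)
  f <- moving_average_filter(sim$trace)
  steady <- 10:nrow(f)
  raw_amp <- diff(range(sim$trace$ax_g[steady]))
  filt_amp <- diff(range(f$A_x[steady]))
  expect_lt(filt_amp, raw_amp)
})

test_that("maneuver specs round-trip through YAML and JSON", {
  spec <- tilt_session_spec(seed = 4)
  ypath <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    segments = lapply(seq_len(nrow(spec$segments)), function(i)
      as.list(spec$segments[i, ])),
    noise_sigma = spec$noise_sigma, seed = spec$seed), ypath)
  back <- read_maneuver(ypath)
  expect_equal(back$segments$target_pitch, spec$segments$target_pitch)
  expect_equal(back$noise_sigma, spec$noise_sigma)
  expect_identical(simulate_trace(back)$trace, simulate_trace(spec)$trace)

  jpath <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(segments = spec$segments, seed = 4),
                       jpath, auto_unbox = TRUE, digits = NA)
  backj <- read_maneuver(jpath, seed = 99)
  expect_equal(backj$seed, 99L)
  expect_equal(backj$segments$duration, spec$segments$duration)
})

test_that("invalid maneuvers are rejected", {
  seg <- data.frame(duration = -1, target_pitch = 0, target_roll = 0,
                    transition = "hold")
  expect_error(maneuver_spec(seg), "positive")
  seg$duration <- 1; seg$target_pitch <- 95
  expect_error(maneuver_spec(seg), "\\[-90, 90\\]")
  seg$target_pitch <- 0; seg$transition <- "ease"
  expect_error(maneuver_spec(seg), "hold")
})
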