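test_that("LED set and message are pure functions of the flags", {
  expect_equal(posture_state()$led, "middle")
  expect_true(is.na(posture_state()$message))
  expect_equal(posture_state("forward")$led, "top")
  expect_equal(posture_state("left")$led, "left")
  expect_equal(posture_state(c("left", "forward"))$led, c("top", "left"))
  # middle LED iff no flag, for every legal flag subset
  for (flags in list(character(0), "forward", "left", "right",
                     c("forward", "left"), c("forward", "right"))) {
    st <- posture_state(flags)
    expect_equal("middle" %in% st$led, length(flags) == 0)
    expect_equal(is.na(st$message), length(flags) == 0)
  }
})

test_that("reminder messages match the phone-display strings", {
  expect_equal(posture_state("right")$message, "Too Right!!")
  expect_equal(posture_state(c("forward", "left"))$message,
               "Too Forward & Left!!")
  expect_equal(posture_state(c("left", "forward"))$message,
               "Too Forward & Left!!")  # forward always listed first
  expect_equal(posture_state("forward")$message, "Too Forward!!")
})

test_that("illegal flag combinations are rejected", {
  expect_error(posture_state(c("left", "right")), "mutually exclusive")
  expect_error(posture_state("backward"), "unknown flag")
})

test_that("assess routes axes to comparators and flags poor posture", {
  th <- build_threshold_set(S_x = 1.0, S_y = 0.0)
  cmps <- build_comparators(th)
  # A_x below Href_x: forward flag, top LED
  res <- assess(A_x = 0.985, A_y = 0, cmps)
  expect_equal(res$state$flags, "forward")
  expect_equal(res$state$led, "top")
  # at the standard values: no flags, middle LED, no message
  res2 <- assess(A_x = 1.0, A_y = 0.0, build_comparators(th))
  expect_equal(res2$state$flags, character(0))
  expect_equal(res2$state$led, "middle")
  expect_true(is.na(res2$state$message))
  # lateral: A_y above Href_yl flags left, below Href_yr flags right
  expect_equal(assess(1, 0.03, build_comparators(th))$state$flags, "left")
  expect_equal(assess(1, -0.03, build_comparators(th))$state$flags, "right")
})

test_that("pathological lateral bands resolve by the side of the standard", {
  # overlapping bands so one input can trip both lateral comparators
  cmps <- list(
    forward = hysteresis_comparator(-10, -9),
    left = hysteresis_comparator(href = -0.01, lref = -0.02),
    right = hysteresis_comparator(href = 0.01, lref = 0.02))
  res <- assess(A_x = 0, A_y = 0.005, cmps, S_y = 0)
  expect_equal(res$state$flags, "left")
  res2 <- assess(A_x = 0, A_y = -0.005, cmps, S_y = 0)
  expect_equal(res2$state$flags, "right")
})

test_that("assess_trace flags a forward tilt and clears on recovery", {
  spec <- tilt_session_spec(seed = 8, pitch = 30)
  sim <- simulate_trace(spec)
  th <- build_threshold_set(S_x = 1.0, S_y = 0.0)
  out <- assess_trace(moving_average_filter(sim$trace), th)
  expect_equal(nrow(out), nrow(sim$trace))
  # flagged while tilted, clear again at the end
  expect_true(any(out$forward == 1))
  expect_equal(out$forward[nrow(out)], 0)
  expect_equal(sum(out$left), 0)
  expect_equal(sum(out$right), 0)
})

test_that("a 30 s held flag with a 10 s interval yields three reminders", {
  t <- seq(0, 29.9, by = 0.1)
  assessments <- data.frame(t_s = t, forward = 1L, left = 0L, right = 0L)
  ev <- emit_reminders(assessments, warning_time = 1, T0 = 10)
  expect_equal(nrow(ev), 3)
  expect_equal(ev$t_s, c(0, 10, 20))
  expect_true(all(ev$message == "Too Forward!!"))
  # warning_time scales the frequency
  ev5 <- emit_reminders(assessments, warning_time = 5, T0 = 10)
  expect_equal(nrow(ev5), 15)
})

test_that("no reminders while flags stay empty; one per isolated flag", {
  t <- seq(0, 9.9, by = 0.1)
  empty <- data.frame(t_s = t, forward = 0L, left = 0L, right = 0L)
  expect_equal(nrow(emit_reminders(empty)), 0)
  single <- data.frame(t_s = 0, forward = 0L, left = 0L, right = 1L)
  ev <- emit_reminders(single)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$message, "Too Right!!")
  expect_equal(ev$flags[[1]], "right")
})

test_that("emit_reminders matches the brute-force scheduler on random streams", {
  set.seed(71)
  for (rep in 1:5) {
    n <- 300
    t <- seq(0, by = 0.1, length.out = n)
    fwd <- as.integer(runif(n) < 0.4)
    lft <- as.integer(runif(n) < 0.2)
    flag_sets <- lapply(seq_len(n), function(k)
      c("forward", "left")[c(fwd[k] == 1, lft[k] == 1)])
    interval <- sample(c(2, 5, 10), 1)
    ev <- emit_reminders(data.frame(t_s = t, forward = fwd, left = lft,
                                    right = 0L),
                         warning_time = 1, T0 = interval)
    expect_equal(ev$t_s, t[oracle_reminders(t, flag_sets, interval)])
  }
})

test_that("reminder events serialize as one JSON object per line", {
  ev <- emit_reminders(data.frame(t_s = c(0, 0.1), forward = c(1L, 1L),
                                  left = c(0L, 1L), right = 0L))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_events_jsonl(ev, path)
  lines <- readLines(path)
  expect_equal(length(lines), 2)
  obj <- jsonlite::fromJSON(lines[2])
  expect_equal(obj$type, "reminder")
  expect_equal(obj$flags, c("forward", "left"))
  expect_equal(obj$message, "Too Forward & Left!!")
})

test_that("emit_reminders validates its inputs", {
  good <- data.frame(t_s = 0:1, forward = 1L, left = 0L, right = 0L)
  expect_error(emit_reminders(good, warning_time = 0), "positive integer")
  bad <- data.frame(t_s = c(1, 0), forward = 1L, left = 0L, right = 0L)
  expect_error(emit_reminders(bad), "time-ordered")
})
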