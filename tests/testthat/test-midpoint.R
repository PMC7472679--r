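test_that("moving average matches its definition at interiors and edges", {
  expect_equal(moving_average(rep(4, 50), 15), rep(4, 50))

  imp <- rep(0, 41)
  imp[21] <- 1
  sm <- moving_average(imp, 15)
  expect_equal(sm[14:28], rep(1 / 15, 15))
  expect_equal(sm[c(13, 29)], c(0, 0))

  ramp <- seq(0, 10, length.out = 51)
  expect_equal(moving_average(ramp, 15)[8:44], ramp[8:44])

  expect_error(moving_average(1:5, 7), "length")
  expect_error(moving_average(1:50, 4), "odd")
})

test_that("second derivative is exact on polynomials, even unevenly sampled", {
  t_even <- seq(0, 10, 0.5)
  y <- 3 * t_even^2
  d2 <- second_derivative(y, t_even)
  expect_equal(d2[2:(length(y) - 1)], rep(6, length(y) - 2))
  expect_true(all(is.na(d2[c(1, length(y))])))

  set.seed(1)
  t_unev <- sort(runif(30, 0, 10))
  y2 <- 2 - t_unev + 0.5 * t_unev^2
  d2u <- second_derivative(y2, t_unev)
  expect_equal(d2u[2:29], rep(1, 28), tolerance = 1e-9)

  lin <- second_derivative(5 - 2 * t_even, t_even)
  expect_equal(lin[2:(length(t_even) - 1)], rep(0, length(t_even) - 2),
               tolerance = 1e-12)

  expect_error(second_derivative(1:4, 1:4), "5")
})

test_that("the second derivative of a sampled logistic changes sign at t0", {
  t <- seq(0, 100, 0.7)
  y <- 12 / (1 + exp(-0.3 * (t - 50)))
  d2 <- second_derivative(y, t)
  before <- d2[!is.na(d2) & t < 48]
  after <- d2[!is.na(d2) & t > 52 & t < 70]
  expect_true(all(before[t[!is.na(d2)] < 48 & t[!is.na(d2)] > 30] > 0))
  expect_true(all(after < 0))
})

test_that("midpoints are recovered to within a beat on noiseless responses", {
  for (k in c(0.2, 0.5)) {
    rec <- responder_recording(A = 12, k = k, noise = 0, seed = 1)
    hemo <- beat_hemodynamics(rec)
    mp <- find_midpoint(hemo, 55)
    expect_true(mp$valid)
    expect_lt(abs(mp$midpoint_time_s - 60), 60 / 90) # one inter-beat interval
  }
})

test_that("a flat segment yields an invalid midpoint, not an error", {
  rec <- quiet_recording(duration_s = 120, heart_rate_bpm = 90)
  hemo <- beat_hemodynamics(rec)
  mp <- find_midpoint(hemo, 55)
  expect_false(mp$valid)
  expect_true(is.na(mp$midpoint_time_s))
})

test_that("midpoint detection degrades gracefully to AoS alone", {
  rec <- responder_recording(noise = 0, seed = 2)
  rec_aos <- rec[, c("time_s", "aortic_pressure")]
  attr(rec_aos, "sampling_rate_hz") <- 1000
  hemo <- beat_hemodynamics(rec_aos)
  expect_true(all(is.na(hemo$CPP)))
  mp <- find_midpoint(hemo, 55)
  expect_true(mp$valid)
  expect_equal(mp$n_signals, 1)
  expect_lt(abs(mp$midpoint_time_s - 60), 2)
})

test_that("median midpoint error stays under 2 s on noisy responses", {
  errs <- vapply(1:20, function(s) {
    rec <- responder_recording(A = 10, k = 0.35, noise = 2, seed = 100 + s)
    mp <- find_midpoint(beat_hemodynamics(rec), 55)
    if (isTRUE(mp$valid)) abs(mp$midpoint_time_s - 60) else Inf
  }, numeric(1))
  expect_lt(median(errs), 2)
})

test_that("normalization zeroes the anchor beat exactly and is idempotent", {
  rec <- responder_recording(seed = 4)
  hemo <- beat_hemodynamics(rec)
  mp <- find_midpoint(hemo, 55)
  norm <- normalize_segment(hemo, mp)

  anchor <- which.min(abs(norm$t))
  expect_identical(norm$MAP_n[anchor], 0)
  expect_identical(norm$AoS_n[anchor], 0)
  expect_identical(norm$AoD_n[anchor], 0)

  again <- normalize_segment(norm, 0)
  expect_equal(again$t, norm$t)
  expect_equal(again$MAP_n, norm$MAP_n)

  invalid <- mp
  invalid$valid <- FALSE
  expect_error(normalize_segment(hemo, invalid), "valid")
})

test_that("a plateaued logistic splits symmetrically about its midpoint", {
  rec <- responder_recording(A = 12, k = 0.5, noise = 0, seed = 6,
                             ventilation_amp_mmHg = 0)
  hemo <- beat_hemodynamics(rec)
  norm <- normalize_segment(hemo, find_midpoint(hemo, 55))
  after <- mean(norm$MAP_n[norm$t > 36 & norm$t < 40])
  before <- mean(norm$MAP_n[norm$t > -40 & norm$t < -36])
  expect_lt(abs(after - 6), 1)
  expect_lt(abs(before + 6), 1)
})

test_that("normalization is invariant to a constant pressure shift", {
  rec <- responder_recording(seed = 8)
  hemo <- beat_hemodynamics(rec)
  mp <- find_midpoint(hemo, 55)
  shifted <- hemo
  shifted$MAP <- hemo$MAP + 17
  shifted$AoS <- hemo$AoS + 17
  shifted$AoD <- hemo$AoD + 17
  expect_equal(normalize_segment(shifted, mp), normalize_segment(hemo, mp))
})

test_that("smoothing configuration validates its windows", {
  expect_error(smoothing_config(window_samples = 4), "odd")
  expect_error(smoothing_config(detection_window_beats = 1), "odd")
})
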