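test_that("beat count matches the generated pulse train", {
  rec <- quiet_recording(duration_s = 60, heart_rate_bpm = 120)
  beats <- detect_beats(rec)
  expect_gte(nrow(beats), 119)
  expect_lte(nrow(beats), 121)
})

test_that("a constant signal is reported pulseless, not an error", {
  expect_warning(
    beats <- detect_beats(rep(60, 5000), rate = 1000),
    "pulseless"
  )
  expect_equal(nrow(beats), 0)
})

test_that("beat counts stay within 2% of truth under noise", {
  rel_err <- vapply(1:20, function(s) {
    rec <- simulate_recording(synth_params(
      duration_s = 60, heart_rate_bpm = 90, noise_sd_mmHg = 2, seed = s
    ))
    truth <- 60 * 90 / 60
    abs(nrow(detect_beats(rec)) - truth) / truth
  }, numeric(1))
  expect_true(all(rel_err <= 0.02))
})

test_that("beat pressures recover analytic extremes and means", {
  # one full sinusoid cycle treated as a single beat
  n <- 1000
  x <- 80 + 20 * sin(2 * pi * (0:(n - 1)) / n)
  one <- tibble::tibble(i_start = 1L, i_end = n + 1L, duration_s = 1)
  h <- beat_pressures(x, one, rate = n)
  expect_equal(h$AoS, 100, tolerance = 1e-3)
  expect_equal(h$AoD, 60, tolerance = 1e-3)
  expect_equal(h$MAP, 80, tolerance = 1e-3)

  # a constant "beat" collapses all three pressures to the constant
  hc <- beat_pressures(rep(72, 500),
                       tibble::tibble(i_start = 1L, i_end = 501L,
                                      duration_s = 0.5),
                       rate = 1000)
  expect_equal(unlist(hc[, c("MAP", "AoS", "AoD")]), c(MAP = 72, AoS = 72,
                                                       AoD = 72))
})

test_that("generator systolic/diastolic levels are recovered within 1 mmHg", {
  rec <- quiet_recording(duration_s = 30, heart_rate_bpm = 90,
                         baseline_map_mmHg = 55, pulse_pressure_mmHg = 30)
  h <- beat_pressures(rec, detect_beats(rec))
  h <- h[-c(1, nrow(h)), ] # edge beats may be clipped
  expect_true(all(abs(h$AoS - h$AoD - 30) < 1))
  expect_true(all(abs(h$MAP - 55) < 1))
})

test_that("beat pressures equal a naive per-beat loop exactly", {
  rec <- responder_recording(duration_s = 20, t_ann = 8, t_mid = 10, seed = 9)
  beats <- detect_beats(rec)
  h <- beat_pressures(rec, beats)
  oracle <- naive_beat_stats(rec$aortic_pressure, beats, rate = 1000)
  # extremes and peak times are bitwise identical; the mean agrees up to
  # floating-point summation order
  expect_identical(h$AoS, oracle$AoS)
  expect_identical(h$AoD, oracle$AoD)
  expect_identical(h$beat_time_s, oracle$beat_time_s)
  expect_equal(h$MAP, oracle$MAP, tolerance = 1e-12)
})

test_that("perfusion pressures follow their reference-channel identities", {
  rec <- quiet_recording(duration_s = 10)
  beats <- detect_beats(rec)
  h <- beat_pressures(rec, beats)

  zero <- rec
  zero$right_atrial_pressure <- 0 * zero$right_atrial_pressure
  zero$intracranial_pressure <- 0 * zero$intracranial_pressure
  perf <- perfusion_pressures(zero, beats, h)
  expect_equal(perf$CPP, h$AoD, tolerance = 1e-12)
  expect_equal(perf$CePP, h$MAP, tolerance = 1e-12)

  offset <- zero
  offset$right_atrial_pressure <- rep(5, nrow(zero))
  perf5 <- perfusion_pressures(offset, beats, h)
  expect_equal(perf5$CPP, h$AoD - 5, tolerance = 1e-12)

  broken <- as.list(rec)
  broken$right_atrial_pressure <- broken$right_atrial_pressure[-1]
  expect_error(perfusion_pressures(broken, beats, h), "length")
})

test_that("pressure ordering AoD <= MAP <= AoS holds on random recordings", {
  for (s in 1:5) {
    rec <- simulate_recording(synth_params(
      duration_s = 40, heart_rate_bpm = sample(seq(60, 150, 10), 1),
      noise_sd_mmHg = runif(1, 0, 3),
      trend = list(type = "linear", slope = runif(1, -0.2, 0.2)),
      seed = s
    ))
    h <- beat_pressures(rec, detect_beats(rec))
    expect_true(all(h$AoD <= h$MAP & h$MAP <= h$AoS))
    expect_true(all(diff(h$beat_time_s) > 0))
  }
})

test_that("beat count is invariant to a constant pressure offset", {
  rec <- responder_recording(duration_s = 30, t_ann = 12, t_mid = 15, seed = 13)
  n1 <- nrow(detect_beats(rec))
  shifted <- rec
  shifted$aortic_pressure <- rec$aortic_pressure + 25
  expect_equal(nrow(detect_beats(shifted)), n1)
})
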