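norm_tbl <- function(t, map = 0 * t, aos = map, aod = map) {
  tibble::tibble(t = t, MAP_n = map, AoS_n = aos, AoD_n = aod)
}

test_that("window means average exactly the beats strictly inside the window", {
  seg <- norm_tbl(seq(-45, 45, 1), map = rep(3, 91))
  expect_equal(window_mean(seg, c(36, 40))$MAP, 3)

  seg2 <- norm_tbl(c(37, 38, 39), map = c(4, 6, 8))
  expect_equal(window_mean(seg2, c(36, 40))$MAP, 6)
  # boundary beats are excluded (open interval)
  seg3 <- norm_tbl(c(36, 38, 40), map = c(100, 6, 100))
  expect_equal(window_mean(seg3, c(36, 40))$MAP, 6)

  expect_warning(wm <- window_mean(seg2, c(-40, -36)), "excluded")
  expect_true(is.na(wm$MAP))
})

test_that("plateaued responses recover their injected amplitude in the windows", {
  rec <- responder_recording(A = 12, k = 0.5, noise = 1, seed = 21)
  hemo <- beat_hemodynamics(rec)
  norm <- normalize_segment(hemo, find_midpoint(hemo, 55))
  delta <- window_mean(norm, c(36, 40))$MAP - window_mean(norm, c(-40, -36))$MAP
  expect_lt(abs(delta - 12), 1)
})

test_that("the paired t test matches the textbook formula", {
  before <- c(1, 2, 3)
  after <- c(2, 4, 5)
  got <- paired_t_test(before, after)
  want <- closed_form_paired_t(before, after)
  expect_equal(got$t, want$t, tolerance = 1e-12)
  expect_equal(got$df, want$df)
  expect_equal(got$p, want$p, tolerance = 1e-12)

  set.seed(7)
  for (i in 1:100) {
    n <- sample(3:50, 1)
    b <- rnorm(n)
    a <- b + rnorm(n, 0.3)
    got <- paired_t_test(b, a)
    want <- closed_form_paired_t(b, a)
    expect_equal(got$t, want$t, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
})

test_that("degenerate or underpowered paired tests error out", {
  expect_error(paired_t_test(1, 2), "at least 2")
  expect_error(paired_t_test(c(1, 2, 3), c(2, 3, 4)), "Degenerate")
  expect_error(paired_t_test(c(1, 2), c(1, 2)), "Degenerate")
})

test_that("Shapiro-Wilk accepts normal and rejects skewed samples", {
  p_norm <- vapply(1:100, function(s) {
    set.seed(s)
    shapiro_wilk(rnorm(500))$p
  }, numeric(1))
  expect_gte(mean(p_norm > 0.05), 0.90)

  p_exp <- vapply(1:100, function(s) {
    set.seed(s)
    shapiro_wilk(rexp(500)^2)$p
  }, numeric(1))
  expect_gte(mean(p_exp < 0.05), 0.95)

  expect_error(shapiro_wilk(rep(1, 10)), "constant")
  expect_error(shapiro_wilk(c(1, 2)), "n")
})

test_that("response classification follows the midpoint-validity rule", {
  counts <- classify_responses(c(5, -3, NA, 2, 8), c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_equal(counts$responder, 3)
  expect_equal(counts$negative_delta, 1)
  expect_equal(counts$no_effect, 1)
  expect_equal(counts$total, 5)
  expect_equal(counts$responder + counts$negative_delta + counts$no_effect,
               counts$total)

  empty <- classify_responses(numeric(), logical())
  expect_equal(unlist(empty), c(responder = 0, negative_delta = 0,
                                no_effect = 0, total = 0))
})

test_that("the scenario suite classifies as constructed", {
  segs <- list()
  valid <- logical()
  deltas <- numeric()
  for (s in 1:5) {
    rec <- responder_recording(A = 10 + s, k = 0.4, noise = 1, seed = 30 + s)
    hemo <- beat_hemodynamics(rec)
    mp <- find_midpoint(hemo, 55)
    valid <- c(valid, mp$valid)
    deltas <- c(deltas, if (mp$valid) {
      norm <- normalize_segment(hemo, mp)
      window_mean(norm, c(36, 40))$MAP - window_mean(norm, c(-40, -36))$MAP
    } else NA_real_)
  }
  flat <- quiet_recording(duration_s = 120, heart_rate_bpm = 90, seed = 99)
  mp_flat <- find_midpoint(beat_hemodynamics(flat), 55)
  valid <- c(valid, mp_flat$valid)
  deltas <- c(deltas, NA_real_)

  counts <- classify_responses(deltas, valid)
  expect_equal(counts$responder, 5)
  expect_equal(counts$negative_delta, 0)
  expect_equal(counts$no_effect, 1)
})

test_that("the response band collapses to zero spread at the anchor", {
  one <- list(norm_tbl(seq(-45, 45, 0.5), map = sin(seq(-45, 45, 0.5) / 10)))
  band1 <- summarize_band(one)
  expect_true(all(band1$sd == 0))

  two <- list(
    norm_tbl(seq(-45, 45, 0.5), map = seq(-45, 45, 0.5) / 5),
    norm_tbl(seq(-45, 45, 0.5), map = -seq(-45, 45, 0.5) / 5)
  )
  band2 <- summarize_band(two)
  expect_equal(band2$mean, rep(0, nrow(band2)), tolerance = 1e-12)
  at0 <- band2[band2$t == 0, ]
  expect_equal(at0$mean, rep(0, 3))
  expect_equal(at0$sd, rep(0, 3))
})

test_that("delta histograms use zero-aligned bins", {
  h1 <- delta_histogram(rep(7, 5), bin_width = 2)
  expect_equal(sum(h1$count > 0), 1)
  expect_equal(h1$count[h1$bin_lo == 6], 5)

  h2 <- delta_histogram(c(-1, 1), bin_width = 2)
  expect_equal(h2$bin_lo, c(-2, 0))
  expect_equal(h2$count, c(1, 1))
  expect_true(any(h2$bin_lo == 0) || any(h2$bin_hi == 0))
})

test_that("comparison objects expose tidy, glance and plots", {
  set.seed(11)
  segs <- lapply(1:6, function(i) {
    norm_tbl(seq(-45, 45, 0.7),
             map = 10 / (1 + exp(-0.4 * seq(-45, 45, 0.7))) - 5 + rnorm(129, 0, 0.2))
  })
  cmp <- compare_boluses(segs)
  td <- tidy(cmp)
  expect_equal(nrow(td), 3)
  expect_true(all(c("pressure", "delta_mean", "t", "p", "shapiro_p") %in%
                    names(td)))
  gl <- glance(cmp)
  expect_equal(gl$n_segments, 6)
  expect_lt(abs(gl$delta_map_mean - 10), 1)
  expect_lt(gl$p_map, 0.05)
  expect_s3_class(autoplot(cmp), "ggplot")
  expect_s3_class(plot_response_band(summarize_band(segs)), "ggplot")
})

test_that("comparison windows validate their orientation", {
  expect_error(comparison_config(before_window = c(-10, 5)), "negative")
  expect_error(comparison_config(after_window = c(-5, 40)), "positive")
  expect_error(comparison_config(before_window = c(-30, -35)), "t_lo")
})
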