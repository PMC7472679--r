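#' Midpoint-recovery study on seeded synthetic segments
#'
#' Simulates single-bolus recordings across an amplitude-by-rate grid under
#' measurement noise and the default ventilation artifact, runs beat
#' detection and midpoint detection on each, and reports the absolute error
#' of the recovered midpoint against the generator's ground truth.
#'
#' @param n_cases Number of simulated segments (the grid is cycled).
#' @param amplitudes_mmHg Logistic amplitudes to cycle through (mmHg).
#' @param rates_per_s Logistic rates to cycle through (1/s).
#' @param noise_sd_mmHg Measurement-noise SD (mmHg).
#' @param seed Master seed; per-case generator seeds are drawn from it.
#' @return A tibble `case`, `amplitude_mmHg`, `rate_per_s`, `valid`,
#'   `abs_error_s` (`Inf` when no midpoint was found).
#' @export
midpoint_recovery_study <- function(n_cases = 100,
                                    amplitudes_mmHg = c(5, 10, 15),
                                    rates_per_s = c(0.2, 0.5),
                                    noise_sd_mmHg = 2,
                                    seed = 1L) {
  grid <- expand.grid(A = amplitudes_mmHg, k = rates_per_s)
  case_seeds <- with_seed(seed, sample.int(.Machine$integer.max, n_cases))
  rows <- purrr::map(seq_len(n_cases), function(i) {
    g <- grid[((i - 1) %% nrow(grid)) + 1, ]
    rec <- simulate_recording(synth_params(
      duration_s = 120, noise_sd_mmHg = noise_sd_mmHg,
      boluses = bolus_truth(55, 60, g$A, g$k), seed = case_seeds[i]
    ))
    mp <- find_midpoint(beat_hemodynamics(rec), 55)
    tibble(
      case = i, amplitude_mmHg = g$A, rate_per_s = g$k,
      valid = mp$valid,
      abs_error_s = if (isTRUE(mp$valid)) abs(mp$midpoint_time_s - 60) else Inf
    )
  })
  dplyr::bind_rows(rows)
}

#' Cohort-level effect-size recovery study
#'
#' For each replicate: draws a cohort of bolus amplitudes from a normal
#' distribution (and rates uniformly), simulates one recording per bolus,
#' runs the full pipeline (beats, segmentation, midpoint, normalization,
#' windowed comparison), and compares the estimated group mean MAP delta
#' with the mean injected amplitude.
#'
#' @param n_seeds Number of replicate cohorts.
#' @param n_boluses Boluses per cohort.
#' @param amp_mean_mmHg,amp_sd_mmHg Amplitude distribution (mmHg).
#' @param rate_range_per_s Uniform range for logistic rates (1/s).
#' @param noise_sd_mmHg Measurement-noise SD (mmHg).
#' @param seed Master seed.
#' @return A tibble `replicate`, `mean_injected`, `mean_estimated`,
#'   `abs_error`, `n_detected`.
#' @export
effect_recovery_study <- function(n_seeds = 50, n_boluses = 37,
                                  amp_mean_mmHg = 12, amp_sd_mmHg = 6,
                                  rate_range_per_s = c(0.2, 0.5),
                                  noise_sd_mmHg = 2,
                                  seed = 1L) {
  rep_seeds <- with_seed(seed, sample.int(.Machine$integer.max, n_seeds))
  cmp <- comparison_config()
  rows <- purrr::map(seq_len(n_seeds), function(r) {
    draws <- with_seed(rep_seeds[r], list(
      A = stats::rnorm(n_boluses, amp_mean_mmHg, amp_sd_mmHg),
      k = stats::runif(n_boluses, rate_range_per_s[1], rate_range_per_s[2]),
      seeds = sample.int(.Machine$integer.max, n_boluses)
    ))
    deltas <- vapply(seq_len(n_boluses), function(i) {
      rec <- simulate_recording(synth_params(
        duration_s = 120, noise_sd_mmHg = noise_sd_mmHg,
        boluses = bolus_truth(55, 60, draws$A[i], draws$k[i]),
        seed = draws$seeds[i]
      ))
      hemo <- beat_hemodynamics(rec)
      mp <- find_midpoint(hemo, 55)
      if (!isTRUE(mp$valid)) return(NA_real_)
      norm <- normalize_segment(hemo, mp)
      window_mean(norm, cmp$after_window)$MAP -
        window_mean(norm, cmp$before_window)$MAP
    }, numeric(1))
    tibble(
      replicate = r,
      mean_injected = mean(draws$A),
      mean_estimated = mean(deltas, na.rm = TRUE),
      abs_error = abs(mean(deltas, na.rm = TRUE) - mean(draws$A)),
      n_detected = sum(!is.na(deltas))
    )
  })
  dplyr::bind_rows(rows)
}

#' Empirical type-I error of the paired t test under a simulated null
#'
#' Draws paired differences from a standard normal (null of no change) and
#' reports the fraction of replicates rejected at `alpha`.
#'
#' @param n Pairs per replicate.
#' @param reps Number of replicates.
#' @param alpha Nominal level.
#' @param seed Master seed.
#' @return A one-row tibble `rejection_rate`, `reps`, `n`.
#' @export
t_test_type1_study <- function(n = 34, reps = 2000, alpha = 0.05, seed = 1L) {
  p <- with_seed(seed, vapply(seq_len(reps), function(r) {
    before <- stats::rnorm(n)
    after <- before + stats::rnorm(n)
    paired_t_test(before, after)$p
  }, numeric(1)))
  tibble(rejection_rate = mean(p < alpha), reps = reps, n = n)
}
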