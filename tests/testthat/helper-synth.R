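# shared fixtures built in code

quiet_recording <- function(duration_s = 60, heart_rate_bpm = 120,
                            seed = 1, ...) {
  simulate_recording(synth_params(
    duration_s = duration_s, heart_rate_bpm = heart_rate_bpm,
    noise_sd_mmHg = 0, ventilation_amp_mmHg = 0, seed = seed, ...
  ))
}

responder_recording <- function(A = 12, k = 0.5, noise = 2, seed = 1,
                                t_ann = 55, t_mid = 60, duration_s = 120,
                                ...) {
  simulate_recording(synth_params(
    duration_s = duration_s, noise_sd_mmHg = noise,
    boluses = bolus_truth(t_ann, t_mid, A, k), seed = seed, ...
  ))
}

calcium_event <- function(time_s = 55, dose = "10 mg") {
  tibble::tibble(time_s = time_s, drug = "calcium", dose = dose)
}

# independent naive per-beat statistics (oracle for beat_pressures)
naive_beat_stats <- function(x, beats, rate, t0 = 0) {
  out <- data.frame(beat_time_s = numeric(0), MAP = numeric(0),
                    AoS = numeric(0), AoD = numeric(0))
  for (r in seq_len(nrow(beats))) {
    lo <- beats$i_start[r]
    hi <- beats$i_end[r] - 1
    seg <- x[lo:hi]
    s <- 0
    mx <- -Inf
    mn <- Inf
    ipk <- lo
    for (j in seq_along(seg)) {
      s <- s + seg[j]
      if (seg[j] > mx) {
        mx <- seg[j]
        ipk <- lo + j - 1
      }
      if (seg[j] < mn) mn <- seg[j]
    }
    out[r, ] <- c(t0 + (ipk - 1) / rate, s / length(seg), mx, mn)
  }
  out
}

# closed-form paired t (textbook formula), independent of stats::t.test
closed_form_paired_t <- function(before, after) {
  d <- after - before
  n <- length(d)
  tstat <- mean(d) / (sd(d) / sqrt(n))
  list(t = tstat, df = n - 1, p = 2 * pt(-abs(tstat), n - 1))
}

# brute-force one-way ANOVA from sums of squares
brute_force_anova <- function(groups) {
  all <- unlist(groups)
  gm <- mean(all)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  dfb <- length(groups) - 1
  dfw <- length(all) - length(groups)
  f <- (ssb / dfb) / (ssw / dfw)
  list(F = f, df_between = dfb, df_within = dfw,
       p = pf(f, dfb, dfw, lower.tail = FALSE))
}
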