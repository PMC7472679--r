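#' Detect individual heartbeats in an aortic pressure signal
#'
#' Detection runs on a band-limited copy of the signal: a short running mean
#' (~50 ms) suppresses measurement noise and a long running mean (~2 s)
#' estimates the baseline (drift plus most of the ventilation artifact); their
#' difference oscillates at the heart rate. Prominence-filtered systolic peaks
#' of that difference define beats; each beat's boundaries sit at the
#' pre-upstroke diastolic troughs flanking the peak. Per-beat pressure
#' summaries ([beat_pressures()]) always use the raw samples.
#'
#' @param aortic A recording tibble (its `aortic_pressure` channel is used) or
#'   a numeric sample vector.
#' @param rate Sampling rate in Hz (taken from the recording when omitted).
#' @param min_excursion_mmHg Pulsatility floor: if the band-limited signal's
#'   robust peak-to-trough excursion is below this, the signal is considered
#'   pulseless and an empty beat table is returned with a warning. Default 5.
#' @param min_beat_s,max_beat_s Physiologic beat-duration bounds (s); beats
#'   outside them are dropped. Defaults 0.25 and 2 (30 kg swine).
#' @return A tibble with one row per beat: `i_start`, `i_end` (1-based sample
#'   indices; the beat spans `i_start:(i_end - 1)`) and `duration_s`. Empty
#'   (zero rows) for pulseless input.
#' @export
detect_beats <- function(aortic, rate = NULL, min_excursion_mmHg = 5,
                         min_beat_s = 0.25, max_beat_s = 2) {
  if (is.data.frame(aortic)) {
    rate <- rate %||% recording_rate(aortic)
    x <- aortic$aortic_pressure
    if (is.null(x)) abort("Recording has no 'aortic_pressure' channel.")
  } else {
    x <- as.numeric(aortic)
  }
  if (is.null(rate)) abort("`rate` is required when `aortic` is a bare vector.")
  stop_if_not_scalar_pos(rate, "rate")
  n <- length(x)
  if (n < 2 * rate) abort("Need at least 2 s of signal to detect beats.")

  empty <- tibble(i_start = integer(), i_end = integer(),
                  duration_s = numeric())

  w_fast <- max(3L, odd_window(round(0.05 * rate)))
  w_slow <- odd_window(round(2 * rate))
  lp <- moving_average(x, min(w_fast, odd_window(n)))
  base <- moving_average(x, min(w_slow, odd_window(n)))
  d <- lp - base

  excursion <- diff(stats::quantile(d, c(0.01, 0.99), names = FALSE))
  if (excursion < min_excursion_mmHg) {
    warn(sprintf(
      "Signal appears pulseless (band-limited excursion %.2f < %.2f mmHg); no beats detected.",
      excursion, min_excursion_mmHg))
    return(empty)
  }

  # candidate local maxima of the band-limited signal above a height floor
  height <- 0.3 * stats::quantile(d, 0.98, names = FALSE)
  core <- d[2:(n - 1)]
  cand <- which(core > d[1:(n - 2)] & core >= d[3:n] & core > height) + 1L
  if (length(cand) == 0) {
    warn("No systolic peaks found above the height floor; no beats detected.")
    return(empty)
  }
  # enforce minimum peak separation, keeping the taller of any close pair
  min_sep <- round(min_beat_s * rate)
  peaks <- integer(length(cand))
  np <- 0L
  for (i in seq_along(cand)) {
    if (np == 0L || cand[i] - peaks[np] >= min_sep) {
      np <- np + 1L
      peaks[np] <- cand[i]
    } else if (d[cand[i]] > d[peaks[np]]) {
      peaks[np] <- cand[i]
    }
  }
  peaks <- peaks[seq_len(np)]
  if (length(peaks) < 2) {
    warn("Fewer than two systolic peaks; no beats delimited.")
    return(empty)
  }

  # boundaries: minimum of the band-limited signal between consecutive peaks,
  # plus a flanking trough one median period before the first / after the last
  period <- round(stats::median(diff(peaks)))
  trough_between <- function(a, b) a - 1L + which.min(d[a:b])
  inner <- purrr::map2_int(peaks[-length(peaks)], peaks[-1], trough_between)
  first <- trough_between(max(1L, peaks[1] - period), peaks[1])
  last <- trough_between(peaks[length(peaks)],
                         min(n, peaks[length(peaks)] + period))
  bounds <- c(first, inner, last)

  beats <- tibble(
    i_start = bounds[-length(bounds)],
    i_end = bounds[-1],
    duration_s = (bounds[-1] - bounds[-length(bounds)]) / rate
  )
  dplyr::filter(beats, .data$duration_s >= min_beat_s,
                .data$duration_s <= max_beat_s)
}

odd_window <- function(w) {
  w <- as.integer(w)
  if (w %% 2L == 0L) w <- w + 1L
  max(w, 3L)
}

#' Per-beat hemodynamic summaries from raw samples
#'
#' For each detected beat: `AoS` = maximum sample (systolic), `AoD` = minimum
#' sample (diastolic), `MAP` = arithmetic mean of all samples in the beat
#' (the true waveform mean, not the 2/3-1/3 approximation), `beat_time_s` =
#' time of the systolic peak.
#'
#' @param aortic Recording tibble or numeric aortic sample vector.
#' @param beats Beat boundary tibble from [detect_beats()].
#' @param rate Sampling rate (Hz); taken from the recording when omitted.
#' @param t0 Time of the first sample (s); taken from the recording when
#'   omitted, else 0.
#' @return A tibble `beat_time_s`, `MAP`, `AoS`, `AoD` (one row per beat,
#'   strictly increasing times, `AoD <= MAP <= AoS`).
#' @export
beat_pressures <- function(aortic, beats, rate = NULL, t0 = NULL) {
  if (is.data.frame(aortic)) {
    rate <- rate %||% recording_rate(aortic)
    t0 <- t0 %||% aortic$time_s[1]
    x <- aortic$aortic_pressure
  } else {
    x <- as.numeric(aortic)
    t0 <- t0 %||% 0
  }
  if (is.null(rate)) abort("`rate` is required when `aortic` is a bare vector.")
  if (nrow(beats) == 0) {
    return(tibble(beat_time_s = numeric(), MAP = numeric(),
                  AoS = numeric(), AoD = numeric()))
  }
  res <- purrr::map2(beats$i_start, beats$i_end, function(a, b) {
    seg <- x[a:(b - 1L)]
    ip <- a - 1L + which.max(seg)
    c(ip, mean(seg), max(seg), min(seg))
  })
  m <- do.call(rbind, res)
  tibble(
    beat_time_s = t0 + (m[, 1] - 1) / rate,
    MAP = m[, 2], AoS = m[, 3], AoD = m[, 4]
  )
}

#' Per-beat coronary and cerebral perfusion pressures
#'
#' Standard resuscitation-literature conventions: `CPP` (coronary perfusion
#' pressure) = aortic diastolic pressure minus the right-atrial pressure at
#' the instant of the aortic diastolic minimum; `CePP` (cerebral perfusion
#' pressure) = beat MAP minus the mean intracranial pressure over the beat.
#'
#' @param recording Recording tibble; needs `right_atrial_pressure` and/or
#'   `intracranial_pressure` channels (a missing channel yields NA for its
#'   pressure, and midpoint detection falls back to the remaining signals).
#' @param beats Beat boundary tibble from [detect_beats()].
#' @param hemo Per-beat pressures from [beat_pressures()] (recomputed when
#'   omitted).
#' @return A tibble `beat_time_s`, `CPP`, `CePP` aligned 1:1 with `hemo`.
#' @export
perfusion_pressures <- function(recording, beats, hemo = NULL) {
  x <- recording[["aortic_pressure"]]
  ra <- recording[["right_atrial_pressure"]]
  icp <- recording[["intracranial_pressure"]]
  if (!is.null(ra) && length(ra) != length(x)) {
    abort("right_atrial_pressure length differs from aortic_pressure.")
  }
  if (!is.null(icp) && length(icp) != length(x)) {
    abort("intracranial_pressure length differs from aortic_pressure.")
  }
  if (is.null(hemo)) hemo <- beat_pressures(recording, beats)
  if (nrow(beats) == 0) {
    return(tibble(beat_time_s = numeric(), CPP = numeric(), CePP = numeric()))
  }
  per_beat <- purrr::map2(beats$i_start, beats$i_end, function(a, b) {
    seg <- x[a:(b - 1L)]
    i_dia <- a - 1L + which.min(seg)
    cpp <- if (is.null(ra)) NA_real_ else min(seg) - ra[i_dia]
    cepp <- if (is.null(icp)) NA_real_ else mean(seg) - mean(icp[a:(b - 1L)])
    c(cpp, cepp)
  })
  m <- do.call(rbind, per_beat)
  tibble(beat_time_s = hemo$beat_time_s, CPP = m[, 1], CePP = m[, 2])
}

#' One-call per-beat hemodynamics for a recording
#'
#' Convenience wrapper: [detect_beats()], [beat_pressures()] and
#' [perfusion_pressures()] in sequence, joined into one beat-level table.
#'
#' @param recording A recording tibble.
#' @inheritParams detect_beats
#' @return A tibble `beat_time_s`, `MAP`, `AoS`, `AoD`, `CPP`, `CePP` (the
#'   perfusion columns are NA when their channels are absent).
#' @export
beat_hemodynamics <- function(recording, min_excursion_mmHg = 5,
                              min_beat_s = 0.25, max_beat_s = 2) {
  beats <- detect_beats(recording, min_excursion_mmHg = min_excursion_mmHg,
                        min_beat_s = min_beat_s, max_beat_s = max_beat_s)
  hemo <- beat_pressures(recording, beats)
  perf <- perfusion_pressures(recording, beats, hemo)
  dplyr::bind_cols(hemo, perf[, c("CPP", "CePP")])
}
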