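#' Ground-truth description of one simulated pressor bolus
#'
#' A pressor response is modelled as a logistic (sigmoid) pressure increment
#' `A / (1 + exp(-k (t - t0)))` superimposed on the arterial channel. The
#' annotation time mimics the injection annotation in the experimental record;
#' the midpoint `t0` is the inflection of the logistic, which the analysis
#' pipeline tries to recover.
#'
#' @param annotation_time_s Time (s, recording clock) at which the bolus is
#'   "given", i.e. would be annotated in the drug-event log.
#' @param midpoint_time_s True logistic inflection time `t0` (s); must not
#'   precede the annotation.
#' @param amplitude_mmHg Logistic asymptote `A` (mmHg). May be zero or
#'   negative (non-responder / depressor).
#' @param rate_per_s Logistic steepness `k` (1/s), strictly positive.
#'
#' @return A one-row tibble with the four ground-truth fields.
#' @export
#' @examples
#' bolus_truth(55, 60, amplitude_mmHg = 12, rate_per_s = 0.5)
bolus_truth <- function(annotation_time_s, midpoint_time_s, amplitude_mmHg,
                        rate_per_s) {
  if (!is.numeric(rate_per_s) || any(rate_per_s <= 0)) {
    abort("`rate_per_s` must be > 0.")
  }
  if (any(midpoint_time_s < annotation_time_s)) {
    abort("`midpoint_time_s` must be >= `annotation_time_s`.")
  }
  tibble(
    annotation_time_s = as.numeric(annotation_time_s),
    midpoint_time_s = as.numeric(midpoint_time_s),
    amplitude_mmHg = as.numeric(amplitude_mmHg),
    rate_per_s = as.numeric(rate_per_s)
  )
}

#' Parameters for the synthetic hemodynamic recording generator
#'
#' Bundles and validates every knob of [simulate_recording()]. Defaults
#' emulate a hypotensive post-resuscitation swine preparation: arterial
#' pressure sampled at 1000 Hz, heart rate 90 bpm, mean arterial pressure
#' around 55 mmHg with a 30 mmHg pulse pressure (systolic in the 70s,
#' diastolic in the 40s, between the <= 50 mmHg systolic shock threshold and
#' full recovery), a 0.25 Hz / 3 mmHg ventilation artifact, and 1 mmHg white
#' measurement noise.
#'
#' @param duration_s Recording length (s), > 0.
#' @param sampling_rate_hz Sample rate (Hz), > 0. Default 1000.
#' @param heart_rate_bpm Heart rate (beats/min), > 0.
#' @param baseline_map_mmHg Beat-mean arterial pressure before drift and
#'   boluses (mmHg).
#' @param pulse_pressure_mmHg Systolic minus diastolic excursion (mmHg), >= 0.
#' @param trend Baseline drift spec: `list(type = "linear", slope = s)` with
#'   `s` in mmHg/s, or `list(type = "exponential", amplitude = a, tau = tau)`
#'   adding `a * (1 - exp(-t / tau))` mmHg (post-resuscitation instability).
#' @param ventilation_freq_hz Ventilation artifact frequency (Hz).
#' @param ventilation_amp_mmHg Ventilation artifact amplitude (mmHg), >= 0.
#' @param noise_sd_mmHg SD of additive white Gaussian noise (mmHg), >= 0.
#' @param boluses Tibble of ground-truth boluses from [bolus_truth()] (may be
#'   empty).
#' @param beat_shape `"asymmetric"` (fast systolic upstroke, exponential
#'   diastolic decay; the default, so beat detection is exercised on realistic
#'   morphology) or `"sinusoid"` (for analytic checks).
#' @param seed Integer seed; identical parameters and seed give bit-identical
#'   recordings.
#'
#' @return A validated list of class `"synth_params"`.
#' @export
synth_params <- function(duration_s = 120,
                         sampling_rate_hz = 1000,
                         heart_rate_bpm = 90,
                         baseline_map_mmHg = 55,
                         pulse_pressure_mmHg = 30,
                         trend = list(type = "linear", slope = 0),
                         ventilation_freq_hz = 0.25,
                         ventilation_amp_mmHg = 3,
                         noise_sd_mmHg = 1,
                         boluses = bolus_truth(numeric(), numeric(),
                                               numeric(), numeric()),
                         beat_shape = c("asymmetric", "sinusoid"),
                         seed = 1L) {
  stop_if_not_scalar_pos(duration_s, "duration_s")
  stop_if_not_scalar_pos(sampling_rate_hz, "sampling_rate_hz")
  stop_if_not_scalar_pos(heart_rate_bpm, "heart_rate_bpm")
  stop_if_not_scalar_pos(pulse_pressure_mmHg, "pulse_pressure_mmHg",
                         strict = FALSE)
  stop_if_not_scalar_pos(ventilation_amp_mmHg, "ventilation_amp_mmHg",
                         strict = FALSE)
  stop_if_not_scalar_pos(noise_sd_mmHg, "noise_sd_mmHg", strict = FALSE)
  beat_shape <- match.arg(beat_shape)
  if (!is.list(trend) || is.null(trend$type) ||
      !trend$type %in% c("linear", "exponential")) {
    abort("`trend` must be list(type = \"linear\", slope = ) or list(type = \"exponential\", amplitude = , tau = ).")
  }
  boluses <- as_tibble(boluses)
  needed <- c("annotation_time_s", "midpoint_time_s", "amplitude_mmHg",
              "rate_per_s")
  if (!all(needed %in% names(boluses))) {
    abort("`boluses` must have columns annotation_time_s, midpoint_time_s, amplitude_mmHg, rate_per_s.")
  }
  if (nrow(boluses) > 0 &&
      (any(boluses$midpoint_time_s < 0) ||
       any(boluses$midpoint_time_s > duration_s))) {
    abort("Bolus midpoints must lie inside the recording [0, duration_s].")
  }
  structure(
    list(
      duration_s = duration_s, sampling_rate_hz = sampling_rate_hz,
      heart_rate_bpm = heart_rate_bpm, baseline_map_mmHg = baseline_map_mmHg,
      pulse_pressure_mmHg = pulse_pressure_mmHg, trend = trend,
      ventilation_freq_hz = ventilation_freq_hz,
      ventilation_amp_mmHg = ventilation_amp_mmHg,
      noise_sd_mmHg = noise_sd_mmHg, boluses = boluses,
      beat_shape = beat_shape, seed = as.integer(seed)
    ),
    class = "synth_params"
  )
}

# Normalized beat morphology on phase [0, 1): 0 at the boundaries (the
# pre-upstroke diastolic trough), 1 at the systolic peak.
beat_shape_fun <- function(phase, shape = "asymmetric", f_up = 0.25,
                           tau = 0.35) {
  if (shape == "sinusoid") {
    return(0.5 - 0.5 * cos(2 * pi * phase))
  }
  up <- phase < f_up
  s <- numeric(length(phase))
  s[up] <- sin(pi / 2 * phase[up] / f_up)
  ph <- phase[!up]
  e1 <- exp(-(ph - f_up) / tau)
  e0 <- exp(-(1 - f_up) / tau)
  s[!up] <- (e1 - e0) / (1 - e0)
  s
}

trend_values <- function(trend, t) {
  if (trend$type == "linear") {
    slope <- trend$slope %||% 0
    slope * t
  } else {
    a <- trend$amplitude %||% 0
    tau <- trend$tau %||% 30
    a * (1 - exp(-t / tau))
  }
}

logistic_sum <- function(boluses, t) {
  out <- numeric(length(t))
  if (nrow(boluses) == 0) return(out)
  for (i in seq_len(nrow(boluses))) {
    out <- out + boluses$amplitude_mmHg[i] /
      (1 + exp(-boluses$rate_per_s[i] * (t - boluses$midpoint_time_s[i])))
  }
  out
}

#' Simulate a multi-channel hemodynamic recording with known ground truth
#'
#' Builds a pulsatile aortic pressure trace as the sum of a periodic beat
#' train, a baseline trend, a ventilation sinusoid, the logistic pressor
#' response of every requested bolus, and white Gaussian noise. Right-atrial
#' and intracranial channels are low-amplitude scaled versions of the same
#' beat clock (enough to compute perfusion pressures; no independent
#' physiology). The per-beat mean of the noiseless, trend-free aortic trace
#' equals `baseline_map_mmHg` and its peak-to-trough excursion equals
#' `pulse_pressure_mmHg`.
#'
#' @param params A [synth_params()] object.
#'
#' @return A tibble of class `"cap_recording"` with columns `time_s`,
#'   `aortic_pressure`, `right_atrial_pressure`, `intracranial_pressure`
#'   (mmHg), and attributes `sampling_rate_hz`, `boluses` (the ground truth,
#'   returned verbatim) and `params`.
#' @seealso [bolus_truth_of()] to retrieve the ground truth,
#'   [write_fixture_suite()] for named validation scenarios.
#' @export
#' @examples
#' p <- synth_params(duration_s = 30, noise_sd_mmHg = 0,
#'                   boluses = bolus_truth(10, 15, 12, 0.5))
#' rec <- simulate_recording(p)
#' head(rec)
simulate_recording <- function(params) {
  if (!inherits(params, "synth_params")) {
    params <- do.call(synth_params, params)
  }
  n <- round(params$duration_s * params$sampling_rate_hz)
  t <- seq.int(0L, n - 1L) / params$sampling_rate_hz
  period <- 60 / params$heart_rate_bpm
  phase <- (t / period) %% 1

  s <- beat_shape_fun(phase, params$beat_shape)
  # offset so the beat-train mean is baseline_map_mmHg
  mean_s <- mean(beat_shape_fun(seq(0, 1, length.out = 4096)[-4096],
                                params$beat_shape))
  pp <- params$pulse_pressure_mmHg
  base <- params$baseline_map_mmHg - pp * mean_s

  drift <- trend_values(params$trend, t)
  vent <- params$ventilation_amp_mmHg *
    sin(2 * pi * params$ventilation_freq_hz * t)
  press <- logistic_sum(params$boluses, t)

  with_seed(params$seed, {
    noise_ao <- if (params$noise_sd_mmHg > 0) {
      rnorm(n, 0, params$noise_sd_mmHg)
    } else {
      numeric(n)
    }
    noise_ra <- if (params$noise_sd_mmHg > 0) {
      rnorm(n, 0, 0.3 * params$noise_sd_mmHg)
    } else {
      numeric(n)
    }
    noise_icp <- if (params$noise_sd_mmHg > 0) {
      rnorm(n, 0, 0.3 * params$noise_sd_mmHg)
    } else {
      numeric(n)
    }
    aortic <- base + pp * s + drift + vent + press + noise_ao
    ra <- 4 + 0.1 * pp * s + 0.3 * vent + noise_ra
    icp <- 10 + 0.05 * pp * s + 0.2 * vent + noise_icp
    rec <- tibble(
      time_s = t,
      aortic_pressure = aortic,
      right_atrial_pressure = ra,
      intracranial_pressure = icp
    )
  })
  attr(rec, "sampling_rate_hz") <- params$sampling_rate_hz
  attr(rec, "boluses") <- params$boluses
  attr(rec, "params") <- params
  class(rec) <- c("cap_recording", class(rec))
  rec
}

#' Retrieve the bolus ground truth attached to a synthetic recording
#'
#' @param recording A recording produced by [simulate_recording()].
#' @return The ground-truth bolus tibble (empty for recordings without one).
#' @export
bolus_truth_of <- function(recording) {
  attr(recording, "boluses") %||%
    bolus_truth(numeric(), numeric(), numeric(), numeric())
}

# named validation scenarios; each returns list(params, events)
scenario_defs <- function(seed = 1L) {
  ca_ev <- function(t, dose = "10 mg") {
    tibble(time_s = t, drug = "calcium", dose = dose)
  }
  list(
    clean_responder = list(
      params = synth_params(
        duration_s = 120, noise_sd_mmHg = 1, seed = seed,
        boluses = bolus_truth(55, 60, 12, 0.5)
      ),
      events = ca_ev(55)
    ),
    drifting_responder = list(
      params = synth_params(
        duration_s = 120, noise_sd_mmHg = 1, seed = seed + 1L,
        trend = list(type = "linear", slope = -0.05),
        boluses = bolus_truth(55, 60, 14, 0.4)
      ),
      events = ca_ev(55)
    ),
    non_responder = list(
      params = synth_params(
        duration_s = 120, noise_sd_mmHg = 1, seed = seed + 2L,
        boluses = bolus_truth(55, 60, 0, 0.5)
      ),
      events = ca_ev(55)
    ),
    rapid_decompensation = list(
      params = synth_params(
        duration_s = 120, noise_sd_mmHg = 1, seed = seed + 3L,
        baseline_map_mmHg = 65,
        trend = list(type = "linear", slope = -0.25),
        boluses = bolus_truth(55, 60, 6, 0.5)
      ),
      events = ca_ev(55)
    ),
    multi_bolus = list(
      params = synth_params(
        duration_s = 300, noise_sd_mmHg = 1, seed = seed + 4L,
        boluses = bolus_truth(c(60, 200), c(65, 205), c(10, 8), c(0.5, 0.4))
      ),
      events = tibble(
        time_s = c(60, 140, 200),
        drug = c("calcium", "epinephrine", "calcium"),
        dose = c("10 mg", "0.5 mg", "10 mg")
      )
    )
  )
}

#' Simulate one named validation scenario
#'
#' @param scenario One of `"clean_responder"`, `"drifting_responder"`,
#'   `"non_responder"`, `"rapid_decompensation"`, `"multi_bolus"`.
#' @param seed Integer seed.
#' @return A list with `recording` (a [simulate_recording()] tibble) and
#'   `events` (a drug-event tibble: `time_s`, `drug`, `dose`).
#' @export
simulate_scenario <- function(scenario = names(scenario_defs()), seed = 1L) {
  scenario <- match.arg(scenario)
  def <- scenario_defs(as.integer(seed))[[scenario]]
  list(recording = simulate_recording(def$params), events = def$events)
}

#' Write the battery of synthetic validation scenarios to disk
#'
#' Emits, for every named scenario, a delimited recording file, a drug-event
#' file, and a ground-truth JSON (`<scenario>_truth.json` with the scenario
#' name, seed, trend slope and the bolus ground truth), in the canonical
#' formats of [read_recording()] and [read_events()].
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed.
#' @return Invisibly, a tibble manifest (`scenario`, `recording`, `events`,
#'   `truth`) of the files written.
#' @export
write_fixture_suite <- function(out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    abort(sprintf("Cannot create output directory '%s'.", out_dir))
  }
  defs <- scenario_defs(as.integer(seed))
  rows <- purrr::imap(defs, function(def, name) {
    sim <- simulate_recording(def$params)
    rec_path <- file.path(out_dir, paste0(name, "_recording.csv"))
    ev_path <- file.path(out_dir, paste0(name, "_events.csv"))
    truth_path <- file.path(out_dir, paste0(name, "_truth.json"))
    write_recording(sim, rec_path)
    readr::write_csv(def$events, ev_path)
    tr <- def$params$trend
    jsonlite::write_json(
      list(
        scenario = name,
        seed = def$params$seed,
        trend_slope_mmHg_per_s = if (tr$type == "linear") tr$slope %||% 0 else NA,
        boluses = def$params$boluses
      ),
      truth_path,
      auto_unbox = TRUE, digits = NA
    )
    tibble(scenario = name, recording = rec_path, events = ev_path,
           truth = truth_path)
  })
  invisible(dplyr::bind_rows(rows))
}
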