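#' Centered moving average with shrinking symmetric edge windows
#'
#' The windowed mean used both for display smoothing of beat-level pressures
#' (to reduce the ventilation artifact) and, before differentiation, for
#' midpoint detection. At position `i` the window is
#' `x[(i - h) : (i + h)]` with `h = (window - 1) / 2`, shrunk symmetrically
#' near the edges so the output stays centered and the same length as the
#' input. O(n) via cumulative sums.
#'
#' @param x Numeric vector.
#' @param window Odd window length, `>= 3`, `<=` `length(x)`.
#' @return Numeric vector, same length as `x`.
#' @export
#' @examples
#' moving_average(c(0, 0, 0, 1, 0, 0, 0), 3)
moving_average <- function(x, window) {
  n <- length(x)
  window <- as.integer(window)
  if (window > n) abort("`window` must not exceed the series length.")
  if (window < 3L || window %% 2L == 0L) abort("`window` must be odd and >= 3.")
  h <- (window - 1L) %/% 2L
  i <- seq_len(n)
  hi_ <- pmin(h, i - 1L, n - i)
  cs <- c(0, cumsum(x))
  (cs[i + hi_ + 1L] - cs[i - hi_]) / (2L * hi_ + 1L)
}

#' Second derivative of a beat-level series on (possibly uneven) times
#'
#' Three-point Lagrange central differences, exact for quadratics on any
#' spacing. The two endpoints are undefined and returned as `NA`.
#'
#' @param y Numeric series (smooth it first; raw beat series are too noisy to
#'   differentiate twice).
#' @param t Strictly increasing times (s), same length as `y`, length >= 5.
#' @return Numeric vector of d2y/dt2, `NA` at both ends.
#' @export
second_derivative <- function(y, t) {
  n <- length(y)
  if (length(t) != n) abort("`y` and `t` must have equal length.")
  if (n < 5) abort("Need at least 5 beats to differentiate twice.")
  if (is.unsorted(t, strictly = TRUE)) abort("`t` must be strictly increasing.")
  i <- 2:(n - 1)
  h1 <- t[i] - t[i - 1]
  h2 <- t[i + 1] - t[i]
  d2 <- 2 * (h2 * y[i - 1] - (h1 + h2) * y[i] + h1 * y[i + 1]) /
    (h1 * h2 * (h1 + h2))
  c(NA_real_, d2, NA_real_)
}

#' Smoothing and midpoint-detection configuration
#'
#' @param window_samples Display smoothing window (beat-level samples),
#'   odd `>= 3`. Default 15.
#' @param detection_window_beats Pre-differentiation smoothing window (beats),
#'   odd `>= 3`. Default 15.
#' @param detection_passes Number of moving-average passes applied before
#'   differentiation. Repeated passes approximate a Gaussian kernel of the
#'   same width with far stronger suppression of the ventilation artifact and
#'   beat-to-beat noise than a single pass; three passes (default) keep even
#'   slow, small responses (5 mmHg at 0.2/s) detectable above the crossing
#'   gate while leaving fast responses intact.
#' @param smooth_d2 Also smooth the second derivative itself (same window)
#'   before locating zero-crossings. Default `TRUE`.
#' @param epsilon_mmHg_s2 Zero-crossing gate: a sign change counts only when
#'   the second derivative reaches beyond +epsilon on one side and -epsilon on
#'   the other, suppressing numerical chatter. Default 0.01 mmHg/s^2.
#' @param max_latency_s Crossings are searched in
#'   `(bolus_time, bolus_time + max_latency_s]`: an IV bolus acts within tens
#'   of seconds, and bounding the search keeps artifact crossings late in the
#'   segment from competing. Default 30 s.
#' @param derivative_scheme Finite-difference scheme; only
#'   `"central_difference"` is implemented.
#' @return A list of class `"smoothing_config"`.
#' @export
smoothing_config <- function(window_samples = 15,
                             detection_window_beats = 15,
                             detection_passes = 3,
                             smooth_d2 = TRUE,
                             epsilon_mmHg_s2 = 0.01,
                             max_latency_s = 30,
                             derivative_scheme = "central_difference") {
  for (w in c(window_samples, detection_window_beats)) {
    if (w < 3 || w %% 2 == 0) abort("Smoothing windows must be odd and >= 3.")
  }
  derivative_scheme <- match.arg(derivative_scheme, "central_difference")
  structure(
    list(window_samples = as.integer(window_samples),
         detection_window_beats = as.integer(detection_window_beats),
         detection_passes = as.integer(detection_passes),
         smooth_d2 = isTRUE(smooth_d2),
         epsilon_mmHg_s2 = epsilon_mmHg_s2,
         max_latency_s = max_latency_s,
         derivative_scheme = derivative_scheme),
    class = "smoothing_config"
  )
}

# repeated-pass moving average, window clipped to the series length
smooth_series <- function(y, window, passes = 1L) {
  w <- min(odd_window(window), odd_window(length(y) - 2L))
  for (p in seq_len(passes)) y <- moving_average(y, w)
  y
}

# zero-crossings of d2 on times t within (t_lo, t_hi], gated at +-eps.
# Returns tibble(time, swing): swing is the net first-derivative change
# mediated by the crossing (integral of d2 over the two bracketing sign-runs),
# a measure of how much slope change this curvature reversal accounts for.
d2_crossings <- function(d2, t, t_lo, t_hi, eps) {
  ok <- which(!is.na(d2))
  if (length(ok) < 3) return(tibble(time = numeric(), swing = numeric()))
  d2v <- d2[ok]
  tv <- t[ok]
  s <- sign(d2v)
  idx <- which(s[-length(s)] * s[-1] < 0)
  if (length(idx) == 0) return(tibble(time = numeric(), swing = numeric()))
  # run ids of constant sign (zeros glue to the previous run)
  run <- cumsum(c(1L, as.integer(s[-1] != s[-length(s)] & s[-1] != 0)))
  res <- purrr::map(idx, function(i) {
    tc <- tv[i] + (tv[i + 1] - tv[i]) * d2v[i] / (d2v[i] - d2v[i + 1])
    if (tc <= t_lo || tc > t_hi) return(NULL)
    left <- run == run[i]
    right <- run == run[i + 1]
    ext_l <- max(abs(d2v[left]))
    ext_r <- max(abs(d2v[right]))
    if (ext_l < eps || ext_r < eps) return(NULL)
    # trapezoidal integral of |d2| over both runs = |slope change| across them
    li <- which(left)
    ri <- which(right)
    seg <- c(li, ri)
    sw <- sum(diff(tv[seg]) * (abs(d2v[seg][-1]) + abs(d2v[seg][-length(seg)])) / 2)
    tibble(time = tc, swing = sw)
  })
  dplyr::bind_rows(res)
}

#' Locate the sigmoid midpoint of a bolus response
#'
#' For each available beat-level signal -- systolic aortic pressure (`AoS`),
#' coronary perfusion pressure (`CPP`) and cerebral perfusion pressure
#' (`CePP`) -- the series is smoothed, differentiated twice on the beat
#' times, and the zero-crossings of the second derivative after the bolus
#' annotation are gathered. Per signal, the crossing mediating the largest
#' curvature swing wins (the dominant change of curvature); the consensus
#' midpoint is the median of the per-signal winners. Signals whose perfusion
#' channels are absent are skipped, so detection degrades gracefully to
#' `AoS` alone.
#'
#' @param beats Beat-level tibble for one bolus segment (`beat_time_s`,
#'   `MAP`, `AoS`, `AoD`, optionally `CPP`, `CePP`).
#' @param bolus_time_s Annotation time of the bolus (s, recording clock).
#' @param config A [smoothing_config()].
#' @return A one-row tibble: `midpoint_time_s`, `crossing_AoS`,
#'   `crossing_CPP`, `crossing_CePP` (NA when a signal yields none),
#'   `n_signals`, `valid`, and the reference pressures `ref_MAP`, `ref_AoS`,
#'   `ref_AoD` at the beat nearest the midpoint. `valid = FALSE` (not an
#'   error) when no signal shows a gated curvature reversal.
#' @export
find_midpoint <- function(beats, bolus_time_s, config = smoothing_config()) {
  out <- tibble(
    midpoint_time_s = NA_real_, crossing_AoS = NA_real_,
    crossing_CPP = NA_real_, crossing_CePP = NA_real_,
    n_signals = 0L, valid = FALSE,
    ref_MAP = NA_real_, ref_AoS = NA_real_, ref_AoD = NA_real_
  )
  t <- beats$beat_time_s
  n_after <- sum(t > bolus_time_s)
  if (length(t) < 5 || n_after < 10) return(out)
  t_hi <- min(max(t), bolus_time_s + config$max_latency_s)

  signals <- c("AoS", "CPP", "CePP")
  for (sig in signals) {
    y <- beats[[sig]]
    if (is.null(y) || anyNA(y)) next
    ys <- smooth_series(y, config$detection_window_beats,
                        config$detection_passes)
    d2 <- second_derivative(ys, t)
    if (config$smooth_d2) {
      ok <- !is.na(d2)
      d2[ok] <- smooth_series(d2[ok], config$detection_window_beats, 1L)
    }
    cr <- d2_crossings(d2, t, bolus_time_s, t_hi, config$epsilon_mmHg_s2)
    if (nrow(cr) > 0) {
      win <- cr$time[which.max(cr$swing)]
      out[[paste0("crossing_", sig)]] <- win
    }
  }
  crossings <- c(out$crossing_AoS, out$crossing_CPP, out$crossing_CePP)
  crossings <- crossings[!is.na(crossings)]
  if (length(crossings) == 0) return(out)
  out$n_signals <- length(crossings)
  out$valid <- TRUE
  out$midpoint_time_s <- stats::median(crossings)
  anchor <- which.min(abs(t - out$midpoint_time_s))
  out$ref_MAP <- beats$MAP[anchor]
  out$ref_AoS <- beats$AoS[anchor]
  out$ref_AoD <- beats$AoD[anchor]
  out
}

#' Normalize a bolus segment to its sigmoid midpoint
#'
#' Re-expresses the beat-level series in the midpoint frame: `t` = beat time
#' minus midpoint time; each pressure minus its value at the beat nearest
#' `t = 0` (the anchor beat, whose normalized values are therefore exactly 0
#' -- no interpolation, so the zero-at-midpoint invariant is exact).
#' Idempotent: normalizing an already-normalized segment with a zero
#' midpoint changes nothing.
#'
#' @param beats Beat-level tibble (`beat_time_s`, `MAP`, `AoS`, `AoD`).
#' @param midpoint A [find_midpoint()] result row (must be valid), or a bare
#'   numeric midpoint time.
#' @return A tibble `t`, `MAP_n`, `AoS_n`, `AoD_n`.
#' @export
normalize_segment <- function(beats, midpoint) {
  mt <- if (is.data.frame(midpoint)) {
    if (!isTRUE(midpoint$valid)) {
      abort("Cannot normalize: midpoint detection was not valid for this segment.")
    }
    midpoint$midpoint_time_s
  } else {
    as.numeric(midpoint)
  }
  # accept a raw beat slice or an already-normalized segment (idempotence)
  tcol <- if ("beat_time_s" %in% names(beats)) "beat_time_s" else "t"
  cols <- if ("MAP" %in% names(beats)) {
    c(MAP = "MAP", AoS = "AoS", AoD = "AoD")
  } else {
    c(MAP = "MAP_n", AoS = "AoS_n", AoD = "AoD_n")
  }
  t <- beats[[tcol]] - mt
  anchor <- which.min(abs(t))
  tibble(
    t = t,
    MAP_n = beats[[cols["MAP"]]] - beats[[cols["MAP"]]][anchor],
    AoS_n = beats[[cols["AoS"]]] - beats[[cols["AoS"]]][anchor],
    AoD_n = beats[[cols["AoD"]]] - beats[[cols["AoD"]]][anchor]
  )
}
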