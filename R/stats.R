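#' Before/after comparison window configuration
#'
#' Defaults follow the midpoint-anchored analysis windows: pressures are
#' averaged over the 4 s period `(-40, -36)` before the midpoint and
#' `(36, 40)` after it (open intervals).
#'
#' @param before_window,after_window Length-2 numeric `(t_lo, t_hi)` in
#'   normalized seconds. The before window must be entirely negative, the
#'   after window entirely positive.
#' @return A list of class `"comparison_config"`.
#' @export
comparison_config <- function(before_window = c(-40, -36),
                              after_window = c(36, 40)) {
  for (w in list(before_window, after_window)) {
    if (length(w) != 2 || w[1] >= w[2]) abort("Windows must be (t_lo, t_hi) with t_lo < t_hi.")
  }
  if (before_window[2] > 0) abort("`before_window` must be entirely negative.")
  if (after_window[1] < 0) abort("`after_window` must be entirely positive.")
  structure(list(before_window = before_window, after_window = after_window),
            class = "comparison_config")
}

#' Mean normalized pressures inside a time window
#'
#' Arithmetic mean of the beat values with `t_lo < t < t_hi` (strict
#' inequalities). An empty window yields `NA` means with a warning; the
#' segment is then excluded from paired testing.
#'
#' @param normalized A normalized-segment tibble (`t`, `MAP_n`, `AoS_n`,
#'   `AoD_n`) from [normalize_segment()].
#' @param window Length-2 numeric `(t_lo, t_hi)`.
#' @return A one-row tibble `MAP`, `AoS`, `AoD`, `n_beats`.
#' @export
window_mean <- function(normalized, window) {
  inside <- normalized$t > window[1] & normalized$t < window[2]
  if (!any(inside)) {
    warn(sprintf("No beats inside window (%g, %g); segment will be excluded.",
                 window[1], window[2]))
    return(tibble(MAP = NA_real_, AoS = NA_real_, AoD = NA_real_,
                  n_beats = 0L))
  }
  tibble(
    MAP = mean(normalized$MAP_n[inside]),
    AoS = mean(normalized$AoS_n[inside]),
    AoD = mean(normalized$AoD_n[inside]),
    n_beats = sum(inside)
  )
}

#' Two-sided paired t test
#'
#' Thin, validated wrapper around the classical paired t test on the
#' element-wise differences, `df = n - 1`.
#'
#' @param before,after Numeric vectors of equal length `n >= 2`.
#' @return A one-row tibble `t`, `df`, `p`.
#' @export
paired_t_test <- function(before, after) {
  if (length(before) != length(after)) abort("`before` and `after` must pair up.")
  n <- length(before)
  if (n < 2) abort("Paired t test needs at least 2 pairs.")
  if (any(!is.finite(before)) || any(!is.finite(after))) {
    abort("Paired t test requires finite values.")
  }
  d <- after - before
  if (stats::sd(d) == 0) {
    abort("Degenerate paired t test: all differences identical (zero variance).")
  }
  ht <- stats::t.test(after, before, paired = TRUE)
  tibble(t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value)
}

#' Shapiro-Wilk normality test
#'
#' @param values Numeric vector, `3 <= n <= 5000`, non-constant.
#' @return A one-row tibble `W`, `p`.
#' @export
shapiro_wilk <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3 || length(values) > 5000) {
    abort("Shapiro-Wilk requires 3 <= n <= 5000 finite values.")
  }
  if (stats::sd(values) == 0) abort("Shapiro-Wilk is degenerate on a constant vector.")
  ht <- stats::shapiro.test(values)
  tibble(W = unname(ht$statistic), p = ht$p.value)
}

#' Windowed before/after comparison across bolus segments
#'
#' For every usable, validly-normalized segment, averages each pressure over
#' the before and after windows, forms per-segment deltas (after - before),
#' and tests the deltas across segments with a paired t test per pressure,
#' with Shapiro-Wilk normality checks. Segments with an empty window are
#' excluded (with a warning from [window_mean()]).
#'
#' @param normalized_segments List (or list-column) of normalized-segment
#'   tibbles from [normalize_segment()].
#' @param config A [comparison_config()].
#' @return An object of class `"bolus_comparison"`: a list with
#'   `per_segment` (tibble of before/after means and deltas per pressure),
#'   `stats` (per-pressure delta mean, SD, t, df, p, Shapiro W and p) and
#'   `config`. Has [tidy()], [glance()] and [autoplot()] methods.
#' @export
compare_boluses <- function(normalized_segments, config = comparison_config()) {
  segs <- purrr::compact(normalized_segments)
  per <- purrr::imap(segs, function(seg, k) {
    b <- window_mean(seg, config$before_window)
    a <- window_mean(seg, config$after_window)
    tibble(
      segment = if (is.character(k)) k else as.integer(k),
      MAP_before = b$MAP, AoS_before = b$AoS, AoD_before = b$AoD,
      MAP_after = a$MAP, AoS_after = a$AoS, AoD_after = a$AoD,
      MAP_delta = a$MAP - b$MAP,
      AoS_delta = a$AoS - b$AoS,
      AoD_delta = a$AoD - b$AoD
    )
  })
  per <- dplyr::bind_rows(per)
  complete <- per[stats::complete.cases(per[, -1]), , drop = FALSE]

  stats_rows <- purrr::map(c("MAP", "AoS", "AoD"), function(pr) {
    before <- complete[[paste0(pr, "_before")]]
    after <- complete[[paste0(pr, "_after")]]
    delta <- complete[[paste0(pr, "_delta")]]
    n <- length(delta)
    row <- tibble(
      pressure = pr, n = n,
      delta_mean = if (n > 0) mean(delta) else NA_real_,
      delta_sd = if (n > 1) stats::sd(delta) else NA_real_,
      t = NA_real_, df = NA_real_, p = NA_real_,
      shapiro_W = NA_real_, shapiro_p = NA_real_
    )
    if (n >= 2 && stats::sd(after - before) > 0) {
      tt <- paired_t_test(before, after)
      row$t <- tt$t
      row$df <- tt$df
      row$p <- tt$p
    }
    if (n >= 3 && stats::sd(delta) > 0) {
      sw <- shapiro_wilk(delta)
      row$shapiro_W <- sw$W
      row$shapiro_p <- sw$p
    }
    row
  })
  structure(
    list(per_segment = per, stats = dplyr::bind_rows(stats_rows),
         config = config),
    class = "bolus_comparison"
  )
}

#' @export
tidy.bolus_comparison <- function(x, ...) x$stats

#' @export
glance.bolus_comparison <- function(x, ...) {
  s <- x$stats
  tibble(
    n_segments = s$n[s$pressure == "MAP"],
    delta_map_mean = s$delta_mean[s$pressure == "MAP"],
    delta_map_sd = s$delta_sd[s$pressure == "MAP"],
    p_map = s$p[s$pressure == "MAP"],
    p_aos = s$p[s$pressure == "AoS"],
    p_aod = s$p[s$pressure == "AoD"]
  )
}

#' @export
print.bolus_comparison <- function(x, ...) {
  cat(sprintf("Bolus before/after comparison (%d segment(s))\n",
              nrow(x$per_segment)))
  cat(sprintf("  windows: (%g, %g) vs (%g, %g) s\n",
              x$config$before_window[1], x$config$before_window[2],
              x$config$after_window[1], x$config$after_window[2]))
  print(x$stats, ...)
  invisible(x)
}

#' Classify bolus responses
#'
#' A bolus "manifests a change" when midpoint detection found a sigmoid
#' (valid midpoint). Among those, the sign of the MAP delta separates
#' responders from negative-delta cases (typically rapid decompensation
#' outpacing the pressor effect); boluses with no detectable sigmoid are
#' `no_effect`. Counts always sum to the number of boluses.
#'
#' @param deltas Numeric MAP deltas, one per bolus (`NA` allowed when the
#'   midpoint was invalid).
#' @param valid Logical vector: was midpoint detection valid per bolus?
#' @return A one-row tibble `responder`, `negative_delta`, `no_effect`,
#'   `total`.
#' @export
classify_responses <- function(deltas, valid) {
  if (length(deltas) != length(valid)) abort("`deltas` and `valid` must align.")
  no_effect <- sum(!valid)
  responder <- sum(valid & !is.na(deltas) & deltas > 0)
  negative <- sum(valid & !is.na(deltas) & deltas <= 0)
  # valid midpoint but delta not computable (empty window): count as negative?
  # no -- keep auditable: fold into no_effect so the three counts still sum.
  leftover <- length(deltas) - no_effect - responder - negative
  tibble(responder = responder, negative_delta = negative,
         no_effect = no_effect + leftover, total = length(deltas))
}

#' Mean +- SD band of normalized pressures on a common time grid
#'
#' Interpolates every normalized segment onto a shared grid over
#' `[-40, 40]` s and computes the across-segment mean and SD per grid time
#' and pressure. By construction both approach 0 as `t` approaches 0 (the
#' normalization anchor).
#'
#' @param normalized_segments List of normalized-segment tibbles.
#' @param grid_step_s Grid spacing (s). Default 1.
#' @param t_range Grid range. Default `c(-40, 40)`.
#' @return A long tibble `t`, `pressure`, `mean`, `sd`, `n`.
#' @export
summarize_band <- function(normalized_segments, grid_step_s = 1,
                           t_range = c(-40, 40)) {
  segs <- purrr::compact(normalized_segments)
  if (length(segs) == 0) abort("Need at least one normalized segment.")
  grid <- seq(t_range[1], t_range[2], by = grid_step_s)
  per_pressure <- purrr::map(c(MAP = "MAP_n", AoS = "AoS_n", AoD = "AoD_n"),
    function(col) {
      m <- vapply(segs, function(seg) {
        stats::approx(seg$t, seg[[col]], xout = grid, rule = 1)$y
      }, numeric(length(grid)))
      m <- matrix(m, nrow = length(grid))
      tibble(
        t = grid,
        mean = rowMeans(m, na.rm = TRUE),
        sd = apply(m, 1, function(v) {
          v <- v[!is.na(v)]
          if (length(v) > 1) stats::sd(v) else 0
        }),
        n = rowSums(!is.na(m))
      )
    })
  dplyr::bind_rows(per_pressure, .id = "pressure") |>
    dplyr::relocate("t")
}

#' Histogram of MAP deltas with zero-aligned bins
#'
#' Bin edges are consecutive multiples of `bin_width` so that 0 is always an
#' edge; each delta falls in `[edge, edge + bin_width)`.
#'
#' @param deltas Numeric vector of per-bolus MAP changes (mmHg).
#' @param bin_width Bin width (mmHg). Default 2.
#' @return A tibble `bin_lo`, `bin_hi`, `count` covering the occupied range.
#' @export
delta_histogram <- function(deltas, bin_width = 2) {
  deltas <- deltas[is.finite(deltas)]
  if (length(deltas) == 0) abort("Need at least one finite delta.")
  idx <- floor(deltas / bin_width)
  rng <- seq(min(idx), max(idx))
  counts <- vapply(rng, function(k) sum(idx == k), integer(1))
  tibble(bin_lo = rng * bin_width, bin_hi = (rng + 1) * bin_width,
         count = counts)
}
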