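#' Cut the beat-level series into per-calcium-bolus segments
#'
#' Each calcium event gets a segment reaching half-way to the neighbouring
#' injection of *any* drug (calcium, epinephrine or bicarbonate) on either
#' side, or to the recording edge when there is none -- isolating the bolus
#' from the effects of other injections. A segment is `usable` when at least
#' `min_context_s` of context exists on both sides of the annotation; shorter
#' segments are retained with `usable = FALSE` so bolus counts stay
#' auditable, and two calcium boluses closer than twice `min_context_s` give
#' two unusable segments, never a merged one.
#'
#' @param events Drug-event tibble (`time_s`, `drug`, `dose`), e.g. from
#'   [read_events()]; sorted by time.
#' @param beats Beat-level tibble (`beat_time_s`, pressures) for the whole
#'   recording.
#' @param span Recording span, `c(t_first, t_last)` in seconds.
#' @param min_context_s Minimum context on each side of the bolus for a
#'   segment to enter the before/after statistics. Default 40 s.
#' @return A tibble with one row per calcium event: `bolus_time_s`, `dose`,
#'   `t_start_s`, `t_end_s`, `context_before_s`, `context_after_s`, `usable`,
#'   and a list-column `beats` holding each segment's beat-level slice
#'   (`beat_time_s` in `[t_start_s, t_end_s]`). Segments are ordered and
#'   pairwise disjoint.
#' @export
segment_boluses <- function(events, beats, span, min_context_s = 40) {
  if (is.unsorted(events$time_s)) {
    events <- events[order(events$time_s), , drop = FALSE]
  }
  ca <- which(events$drug == "calcium")
  out <- tibble(
    bolus_time_s = numeric(), dose = character(),
    t_start_s = numeric(), t_end_s = numeric(),
    context_before_s = numeric(), context_after_s = numeric(),
    usable = logical(), beats = list()
  )
  if (length(ca) == 0) return(out)
  if (any(events$time_s[ca] < span[1] | events$time_s[ca] > span[2])) {
    abort("Calcium event outside the recording span.")
  }
  rows <- purrr::map(ca, function(i) {
    t_i <- events$time_s[i]
    t_prev <- if (i > 1) events$time_s[i - 1] else NA_real_
    t_next <- if (i < nrow(events)) events$time_s[i + 1] else NA_real_
    t_start <- if (is.na(t_prev)) span[1] else (t_prev + t_i) / 2
    t_end <- if (is.na(t_next)) span[2] else (t_i + t_next) / 2
    slice <- beats[beats$beat_time_s >= t_start & beats$beat_time_s <= t_end, ,
                   drop = FALSE]
    tibble(
      bolus_time_s = t_i, dose = events$dose[i],
      t_start_s = t_start, t_end_s = t_end,
      context_before_s = t_i - t_start, context_after_s = t_end - t_i,
      usable = (t_i - t_start) >= min_context_s &&
        (t_end - t_i) >= min_context_s,
      beats = list(slice)
    )
  })
  dplyr::bind_rows(rows)
}
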