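#' Full run configuration for the bolus-response pipeline
#'
#' @param channel_map Optional named vector mapping file columns to channel
#'   roles (see [read_recording()]).
#' @param smoothing A [smoothing_config()].
#' @param comparison A [comparison_config()].
#' @param min_context_s Minimum context per side for a usable segment (s).
#' @param min_excursion_mmHg Pulsatility floor for beat detection (mmHg).
#' @param seed Integer seed governing any randomness in a run.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(channel_map = NULL,
                       smoothing = smoothing_config(),
                       comparison = comparison_config(),
                       min_context_s = 40,
                       min_excursion_mmHg = 5,
                       seed = 1L) {
  structure(
    list(channel_map = channel_map, smoothing = smoothing,
         comparison = comparison, min_context_s = min_context_s,
         min_excursion_mmHg = min_excursion_mmHg, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Analyze a recording in memory: beats, segments, midpoints, comparison
#'
#' Runs the full analysis chain on an already-loaded recording and event
#' table: beat detection, per-beat hemodynamics (with perfusion pressures
#' when the channels exist), per-calcium-bolus segmentation, sigmoid-midpoint
#' detection, midpoint normalization, windowed before/after comparison, and
#' response classification. Deterministic for fixed inputs and config.
#'
#' @param recording Recording tibble (from [read_recording()] or
#'   [simulate_recording()]).
#' @param events Drug-event tibble (from [read_events()]).
#' @param config A [run_config()].
#' @return A list: `beats` (beat-level tibble), `segments` (per-bolus tibble
#'   with `midpoint_*` columns and `normalized` list-column), `normalized`
#'   (alias of `segments`), `comparison` (a `"bolus_comparison"`, NULL when
#'   no usable segment), `classification` (counts tibble) and `summary`
#'   (plain list ready for JSON).
#' @export
analyze_recording <- function(recording, events, config = run_config()) {
  hemo <- beat_hemodynamics(recording,
                            min_excursion_mmHg = config$min_excursion_mmHg)
  span <- recording_span(recording)
  segments <- segment_boluses(events, hemo, span,
                              min_context_s = config$min_context_s)

  if (nrow(segments) == 0) {
    summary <- list(n_boluses = 0L, n_usable = 0L, note = "no calcium events")
    return(list(beats = hemo, segments = segments, normalized = segments,
                comparison = NULL,
                classification = classify_responses(numeric(), logical()),
                summary = summary))
  }

  mids <- dplyr::bind_rows(purrr::map2(
    segments$beats, segments$bolus_time_s,
    function(b, t0) find_midpoint(b, t0, config$smoothing)
  ))
  names(mids)[names(mids) != "midpoint_time_s"] <-
    paste0("midpoint_", names(mids)[names(mids) != "midpoint_time_s"])
  segments <- dplyr::bind_cols(segments, mids)
  segments$normalized <- purrr::pmap(
    list(segments$beats, segments$midpoint_time_s,
         segments$midpoint_valid, segments$usable),
    function(b, mt, valid, usable) {
      if (isTRUE(valid) && isTRUE(usable)) normalize_segment(b, mt) else NULL
    }
  )

  usable_norm <- purrr::compact(segments$normalized)
  comparison <- if (length(usable_norm) > 0) {
    compare_boluses(usable_norm, config$comparison)
  } else {
    NULL
  }

  # per-bolus MAP deltas aligned with all boluses (NA when not normalized)
  deltas <- rep(NA_real_, nrow(segments))
  if (!is.null(comparison)) {
    idx <- which(!purrr::map_lgl(segments$normalized, is.null))
    deltas[idx] <- comparison$per_segment$MAP_delta
  }
  classification <- classify_responses(deltas, segments$midpoint_valid)

  summary <- list(
    n_boluses = nrow(segments),
    n_usable = sum(segments$usable),
    n_valid_midpoint = sum(segments$midpoint_valid),
    counts = as.list(classification[, c("responder", "negative_delta",
                                        "no_effect")]),
    classification_rule = paste(
      "responder: valid midpoint and MAP delta > 0;",
      "negative_delta: valid midpoint and MAP delta <= 0;",
      "no_effect: no detectable sigmoid (one defensible reading of",
      "'manifested a change')"
    )
  )
  if (!is.null(comparison)) {
    s <- comparison$stats
    for (pr in s$pressure) {
      r <- s[s$pressure == pr, ]
      key <- tolower(pr)
      summary[[paste0("delta_", key, "_mean")]] <- r$delta_mean
      summary[[paste0("delta_", key, "_sd")]] <- r$delta_sd
      summary[[paste0("t_", key)]] <- r$t
      summary[[paste0("p_", key)]] <- r$p
      summary[[paste0("shapiro_p_", key)]] <- r$shapiro_p
    }
    summary$delta_map <- summary$delta_map_mean
    summary$p_map <- summary$p_map %||% NA_real_
  }

  list(beats = hemo, segments = segments, normalized = segments,
       comparison = comparison, classification = classification,
       summary = summary)
}

#' Run the pipeline from files and write all artifacts
#'
#' Reads the recording and drug events, calls [analyze_recording()], and
#' writes the segment manifest, per-bolus normalized tables, `summary.json`,
#' the mean +- SD response-band figure and the MAP-delta histogram into
#' `out_dir`, together with a copy of the configuration
#' (`run_config.json`) so a run can be reproduced from its output directory.
#'
#' @param recording_path Path to a recording file.
#' @param events_path Path to a drug-event file.
#' @param out_dir Output directory.
#' @param config A [run_config()].
#' @return The [analyze_recording()] result list, invisibly.
#' @export
run_analysis <- function(recording_path, events_path, out_dir,
                         config = run_config()) {
  recording <- read_recording(recording_path, config$channel_map)
  events <- read_events(events_path)
  results <- analyze_recording(recording, events, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_outputs(results, out_dir)

  jsonlite::write_json(
    list(
      min_context_s = config$min_context_s,
      min_excursion_mmHg = config$min_excursion_mmHg,
      seed = config$seed,
      smoothing = unclass(config$smoothing),
      comparison = unclass(config$comparison),
      channel_map = as.list(config$channel_map %||% list())
    ),
    file.path(out_dir, "run_config.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )

  norm <- purrr::compact(results$segments$normalized)
  if (length(norm) > 0) {
    band <- summarize_band(norm)
    readr::write_csv(band, file.path(out_dir, "response_band.csv"))
    ggplot2::ggsave(file.path(out_dir, "response_band.png"),
                    plot_response_band(band), width = 6, height = 6, dpi = 150)
    deltas <- results$comparison$per_segment$MAP_delta
    deltas <- deltas[is.finite(deltas)]
    if (length(deltas) > 0) {
      h <- delta_histogram(deltas)
      readr::write_csv(h, file.path(out_dir, "delta_histogram.csv"))
      ggplot2::ggsave(file.path(out_dir, "delta_histogram.png"),
                      plot_delta_histogram(h), width = 5, height = 4,
                      dpi = 150)
    }
  }
  invisible(results)
}
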