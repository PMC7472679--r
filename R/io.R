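#' Read a multi-channel pressure recording from delimited text
#'
#' Canonical format: one header row; first column `time_s` (seconds from
#' recording start, 0-based, uniform); remaining columns named channels in
#' mmHg. An aortic pressure channel is mandatory; right-atrial and
#' intracranial channels enable perfusion-pressure computation when present.
#'
#' @param path Path to a delimited text file (comma- or tab-separated).
#' @param channel_map Optional named character vector mapping file column
#'   names to canonical roles, e.g.
#'   `c(AoP = "aortic_pressure", RA = "right_atrial_pressure")`. Columns
#'   already named with canonical roles need no mapping.
#' @return A `"cap_recording"` tibble (`time_s` plus channel columns) with a
#'   `sampling_rate_hz` attribute inferred from the time column.
#' @export
read_recording <- function(path, channel_map = NULL) {
  if (!file.exists(path)) abort(sprintf("Recording file '%s' not found.", path))
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  # base parser: exact strtod, so written recordings round-trip bit-for-bit
  rec <- tryCatch(
    as_tibble(utils::read.table(path, header = TRUE, sep = sep)),
    error = function(e) abort(sprintf("Failed to parse '%s': %s", path,
                                      conditionMessage(e)))
  )
  if (ncol(rec) < 2) abort("Recording must have a time column and at least one channel.")
  names(rec)[1] <- "time_s"
  if (!is.null(channel_map)) {
    hit <- names(rec) %in% names(channel_map)
    names(rec)[hit] <- unname(channel_map[names(rec)[hit]])
  }
  if (!"aortic_pressure" %in% names(rec)) {
    abort("Recording lacks the required 'aortic_pressure' channel (use `channel_map` to map a column to it).")
  }
  bad <- !vapply(rec, is.numeric, logical(1))
  if (any(bad)) {
    abort(sprintf("Non-numeric recording column(s): %s (ragged or corrupt rows?).",
                  paste(names(rec)[bad], collapse = ", ")))
  }
  if (any(!is.finite(rec$time_s)) || is.unsorted(rec$time_s, strictly = TRUE)) {
    abort("Time column must be finite and strictly increasing.")
  }
  dt <- diff(rec$time_s)
  rate <- 1 / stats::median(dt)
  attr(rec, "sampling_rate_hz") <- rate
  class(rec) <- c("cap_recording", class(rec))
  inform(sprintf("Read recording: %d samples, %d channel(s), %.6g Hz.",
                 nrow(rec), ncol(rec) - 1L, rate))
  rec
}

#' Write a recording in the canonical delimited format
#'
#' Times are written with enough digits to round-trip bit-exactly through
#' [read_recording()].
#'
#' @param recording A recording tibble (`time_s` + channel columns).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  df <- as.data.frame(recording)
  # 17 significant digits: every double survives the text round-trip exactly
  for (col in names(df)) {
    if (is.double(df[[col]])) df[[col]] <- sprintf("%.17g", df[[col]])
  }
  tryCatch(
    readr::write_csv(df, path),
    error = function(e) abort(sprintf("Failed to write recording to '%s': %s",
                                      path, conditionMessage(e)))
  )
  invisible(path)
}

.drugs <- c("calcium", "epinephrine", "bicarbonate")

#' Read drug-event annotations
#'
#' Expects a delimited file with columns `time_s`, `drug`, `dose`. Drugs must
#' be one of `calcium`, `epinephrine`, `bicarbonate`. Events are returned
#' sorted by time; ties keep file order.
#'
#' @param path Path to the event file.
#' @return A tibble with columns `time_s` (numeric seconds), `drug`
#'   (character), `dose` (character, magnitude + unit, e.g. `"10 mg"`).
#' @export
read_events <- function(path) {
  if (!file.exists(path)) abort(sprintf("Event file '%s' not found.", path))
  ev <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(
                            time_s = readr::col_character(),
                            drug = readr::col_character(),
                            dose = readr::col_character()
                          ))
  if (!all(c("time_s", "drug", "dose") %in% names(ev))) {
    abort("Event file must have columns time_s, drug, dose.")
  }
  t_num <- suppressWarnings(as.numeric(ev$time_s))
  if (any(is.na(t_num) & !is.na(ev$time_s))) {
    abort(sprintf("Unparseable event time at row(s): %s.",
                  paste(which(is.na(t_num) & !is.na(ev$time_s)), collapse = ", ")))
  }
  ev$time_s <- t_num
  ev$drug <- tolower(trimws(ev$drug))
  bad <- !ev$drug %in% .drugs
  if (any(bad)) {
    abort(sprintf("Unknown drug name(s): %s (allowed: %s).",
                  paste(unique(ev$drug[bad]), collapse = ", "),
                  paste(.drugs, collapse = ", ")))
  }
  ev[order(ev$time_s), , drop = FALSE]
}

#' Write pipeline outputs to a directory
#'
#' Emits one normalized-segment table per usable bolus
#' (`segment_<k>_normalized.csv`: `t_normalized_s`, `MAP`, `AoS`, `AoD`), a
#' segment manifest (`segments.csv`), and a `summary.json` holding group
#' deltas, test statistics and classification counts. Deterministic: the same
#' results object always produces byte-identical tables.
#'
#' @param results A result list from [analyze_recording()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) abort(sprintf("Cannot create '%s'.", out_dir))
  paths <- character()

  manifest <- results$segments |>
    dplyr::select(dplyr::any_of(c("bolus_time_s", "dose", "t_start_s",
                                  "t_end_s", "context_before_s",
                                  "context_after_s", "usable")))
  p <- file.path(out_dir, "segments.csv")
  readr::write_csv(manifest, p)
  paths <- c(paths, p)

  norm <- results$normalized
  if (!is.null(norm) && nrow(norm) > 0) {
    for (k in seq_len(nrow(norm))) {
      seg <- norm$normalized[[k]]
      if (is.null(seg)) next
      tab <- tibble(t_normalized_s = seg$t, MAP = seg$MAP_n,
                    AoS = seg$AoS_n, AoD = seg$AoD_n)
      p <- file.path(out_dir, sprintf("segment_%d_normalized.csv", k))
      readr::write_csv(tab, p)
      paths <- c(paths, p)
    }
  }

  p <- file.path(out_dir, "summary.json")
  jsonlite::write_json(results$summary, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  paths <- c(paths, p)
  invisible(paths)
}
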