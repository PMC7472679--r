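#' Paths to the packaged blood-chemistry fixtures
#'
#' `"panel"` is the per-animal-per-round transcription of the three-cohort
#' blood-gas record (pH, ionized calcium, and per-round calcium/epinephrine
#' injection counts for cohort 3); `"reference"` is the published two-decimal
#' summary of the cohort 1-2 chemistries used by [chemistry_report()].
#'
#' @param which `"panel"` or `"reference"`.
#' @return A file path.
#' @export
chemistry_fixture_path <- function(which = c("panel", "reference")) {
  which <- match.arg(which)
  fn <- switch(which,
               panel = "blood_chemistry.csv",
               reference = "blood_chem_reference_summary.csv")
  system.file("extdata", fn, package = "capressor", mustWork = TRUE)
}

.max_round <- c(`1` = 5L, `2` = 4L, `3` = 4L)

#' Load and validate blood-chemistry records
#'
#' Reads the tidy per-animal-per-round panel. `status = "missing"` marks
#' rounds whose chemistry was drawn but lost (kept as rows, excluded from
#' aggregation); rounds an animal did not survive to are simply absent.
#' Validation: cohort 1 has at most 5 experimental rounds, cohorts 2-3 at
#' most 4; ionized calcium must be positive when present.
#'
#' @param path CSV path; defaults to the packaged fixture.
#' @return A tibble `cohort`, `animal`, `round` (`"baseline"`, `"1"`, ...),
#'   `pH`, `iCa` (mmol/L), `bolus_ca`, `epi` (counts, cohort 3 only),
#'   `status`, `suspect`.
#' @export
load_chemistry <- function(path = chemistry_fixture_path()) {
  rec <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(
                           cohort = readr::col_integer(),
                           animal = readr::col_integer(),
                           round = readr::col_character(),
                           pH = readr::col_double(),
                           iCa = readr::col_double(),
                           bolus_ca = readr::col_integer(),
                           epi = readr::col_integer(),
                           status = readr::col_character(),
                           suspect = readr::col_logical()
                         ))
  if (!all(rec$cohort %in% 1:3)) abort("Cohort must be 1, 2 or 3.")
  rnum <- suppressWarnings(as.integer(rec$round))
  bad <- which(!(rec$round == "baseline" |
                   (!is.na(rnum) & rnum >= 1 &
                      rnum <= .max_round[as.character(rec$cohort)])))
  if (length(bad) > 0) {
    abort(sprintf("Invalid round/cohort combination at row(s): %s.",
                  paste(bad, collapse = ", ")))
  }
  if (any(rec$iCa <= 0, na.rm = TRUE)) abort("iCa must be positive when present.")
  if (!all(rec$status %in% c("ok", "missing"))) {
    abort("status must be 'ok' or 'missing'.")
  }
  rec
}

chem_group <- function(round) {
  dplyr::case_when(
    round == "baseline" ~ "baseline",
    round == "1" ~ "round1",
    TRUE ~ "other"
  )
}

#' Aggregate blood chemistries into baseline / round 1 / other rounds
#'
#' Arithmetic mean and sample (n - 1) SD per analyte over non-missing records
#' in each group: baseline, round 1, and all rounds >= 2 pooled. A group with
#' a single value reports `sd = NA` (sample SD undefined).
#'
#' @param records Tibble from [load_chemistry()] (filter to the cohorts of
#'   interest first, e.g. `dplyr::filter(records, cohort %in% 1:2)`).
#' @param analytes Character vector of analyte columns. Default pH and iCa.
#' @return A tibble `group`, `analyte`, `n`, `mean`, `sd` with groups ordered
#'   baseline, round1, other.
#' @export
aggregate_chemistry <- function(records, analytes = c("pH", "iCa")) {
  if (nrow(records) == 0) abort("No chemistry records to aggregate.")
  records |>
    dplyr::mutate(group = chem_group(.data$round)) |>
    tidyr::pivot_longer(dplyr::all_of(analytes), names_to = "analyte",
                        values_to = "value") |>
    dplyr::filter(.data$status == "ok", !is.na(.data$value)) |>
    dplyr::group_by(group = factor(.data$group,
                                   c("baseline", "round1", "other")),
                    analyte = factor(.data$analyte, analytes)) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sd = if (dplyr::n() > 1) stats::sd(.data$value) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(group = as.character(.data$group),
                  analyte = as.character(.data$analyte))
}

#' Classical fixed-effects one-way ANOVA on a list of groups
#'
#' @param groups List of >= 2 numeric vectors, each with n >= 2.
#' @return A one-row tibble `F`, `df_between`, `df_within`, `p`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2) abort("Need at least 2 groups.")
  sizes <- lengths(groups)
  if (any(sizes < 2)) abort("Every group needs n >= 2.")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), sizes))
  fit <- stats::aov(values ~ g)
  s <- summary(fit)[[1]]
  tibble(F = s$`F value`[1], df_between = s$Df[1], df_within = s$Df[2],
         p = s$`Pr(>F)`[1])
}

#' One-way ANOVA of an analyte across baseline / round 1 / later rounds
#'
#' Builds the three comparison groups from the chemistry records and runs
#' [one_way_anova()]. By default the later rounds (>= 2) are first averaged
#' within each animal ("average remaining post 2+ rounds"), so each animal
#' contributes one value to that group; `rounds2plus = "pooled"` instead
#' enters every round-2+ record individually.
#'
#' @param records Chemistry records (filter to cohorts of interest first).
#' @param analyte Analyte column name. Default `"iCa"`.
#' @param rounds2plus `"per_animal"` (default) or `"pooled"`.
#' @return A one-row tibble `F`, `df_between`, `df_within`, `p`.
#' @export
chemistry_anova <- function(records, analyte = "iCa",
                            rounds2plus = c("per_animal", "pooled")) {
  rounds2plus <- match.arg(rounds2plus)
  rec <- records |>
    dplyr::mutate(group = chem_group(.data$round),
                  value = .data[[analyte]]) |>
    dplyr::filter(.data$status == "ok", !is.na(.data$value))
  other <- rec |> dplyr::filter(.data$group == "other")
  other_vals <- if (rounds2plus == "per_animal") {
    other |>
      dplyr::group_by(.data$cohort, .data$animal) |>
      dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
      dplyr::pull("value")
  } else {
    other$value
  }
  one_way_anova(list(
    baseline = rec$value[rec$group == "baseline"],
    round1 = rec$value[rec$group == "round1"],
    other = other_vals
  ))
}

#' Compare recomputed chemistry summaries against the published reference
#'
#' Recomputes the cohort 1-2 group summaries from the per-animal panel,
#' rounds them to the reference's two decimals, and flags every cell that
#' disagrees with the published value. Discrepancies are reported, never
#' silently matched: the pooled rounds-2+ cells are known not to survive
#' recomputation from the printed per-animal panel.
#'
#' @param records Chemistry records; defaults to the packaged panel
#'   restricted to cohorts 1-2.
#' @param reference_path Path to the reference summary CSV.
#' @return A tibble with computed and reference mean/SD per group and
#'   analyte, plus logical `mean_matches` and `sd_matches`.
#' @export
chemistry_report <- function(records = NULL,
                             reference_path = chemistry_fixture_path("reference")) {
  if (is.null(records)) {
    records <- dplyr::filter(load_chemistry(), .data$cohort %in% 1:2)
  }
  comp <- aggregate_chemistry(records)
  ref <- readr::read_csv(reference_path, comment = "#",
                         show_col_types = FALSE)
  dplyr::inner_join(comp, ref, by = c("group", "analyte"),
                    suffix = c("_computed", "_reference")) |>
    dplyr::mutate(
      mean_matches = round(.data$mean_computed, 2) == .data$mean_reference,
      sd_matches = round(.data$sd_computed, 2) == .data$sd_reference,
      n_matches = .data$n_computed == .data$n_reference
    )
}
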