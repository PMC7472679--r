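Package: capressor
Title: Beat-by-Beat Analysis of Calcium Pressor Responses in Arterial
    Pressure Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the pressor response to intravenous
    calcium boluses in continuous arterial pressure recordings from
    hypotensive, post-resuscitation animals. Detects individual heartbeats
    in the aortic pressure waveform, computes per-beat hemodynamics (mean,
    systolic and diastolic aortic pressure, coronary and cerebral perfusion
    pressure), isolates per-bolus segments half-way to neighbouring drug
    injections, locates the midpoint of the sigmoid pressor response via
    second-derivative zero-crossings, normalizes each response to the
    (t = 0, dP = 0) midpoint frame, and compares windowed before/after
    pressures with paired t tests. Includes a ground-truthed synthetic
    waveform generator (pulsatile beat train, ventilation artifact,
    baseline drift, logistic pressor responses) for validation, and
    aggregation plus one-way ANOVA of longitudinal blood-gas panels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
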