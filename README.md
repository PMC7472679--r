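# capressor

Beat-by-beat analysis of calcium pressor responses in arterial pressure
recordings from hypotensive, post-resuscitation animals.

## The problem

After resuscitation from pseudo-pulseless electrical activity (pseudo-PEA),
animals are frequently hypotensive and refractory to catecholamine pressors;
boluses of intravenous calcium can produce a pressor response. The response
is well approximated by a logistic curve in time,

```
P(t) = P0(t) + A / (1 + exp(-k (t - t0)))
```

with amplitude *A* (mmHg), rate *k* (1/s) and midpoint *t0* — but it rides
on an unstable, drifting baseline *P0(t)* overlaid with a ventilation
artifact, so raw pressures cannot simply be averaged across boluses.

`capressor` is for physiologists and resuscitation researchers who need to
quantify such drug responses from continuous pressure recordings. It:

* detects individual heartbeats in the aortic waveform and computes per-beat
  hemodynamics — mean (MAP), systolic (AoS) and diastolic (AoD) aortic
  pressure, plus coronary (CPP = AoD − right-atrial at diastole) and
  cerebral (CePP = MAP − mean intracranial) perfusion pressures;
* isolates each calcium bolus in a segment reaching half-way to the
  neighbouring injection of any drug;
* locates the response midpoint *t0* at the zero-crossing of the second
  derivative of smoothed beat-level series (AoS, CPP, CePP; median
  consensus), and normalizes each segment so the midpoint sits at
  (t = 0, ΔP = 0);
* averages the normalized pressures over the windows (−40, −36) s and
  (36, 40) s around the midpoint and compares them with a paired t test;
* aggregates longitudinal blood-gas panels (pH, ionized calcium) by
  experimental round and tests the across-round decline with one-way ANOVA;
* ships a ground-truthed synthetic waveform generator (pulsatile beat train,
  baseline drift, ventilation artifact, logistic responses, noise) so every
  stage is validated against known truth.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` on comparison objects, ggplot2 figures.

## Worked example

Simulate six bolus responses with known amplitudes, run the full chain, and
compare the windows:

```r
library(capressor)

norm <- lapply(1:6, function(i) {
  rec <- simulate_recording(synth_params(
    duration_s = 120, noise_sd_mmHg = 2,
    boluses = bolus_truth(55, 60, c(14, 9, 16, 7, 12, 11)[i], 0.2 + 0.05 * i),
    seed = i))
  hemo <- beat_hemodynamics(rec)                 # beats -> MAP/AoS/AoD/CPP/CePP
  mp   <- find_midpoint(hemo, bolus_time_s = 55) # sigmoid inflection
  normalize_segment(hemo, mp)                    # (t = 0, dP = 0) frame
})
compare_boluses(norm)
#> Bolus before/after comparison (6 segment(s))
#>   windows: (-40, -36) vs (36, 40) s
#> # A tibble: 3 x 9
#>   pressure     n delta_mean delta_sd     t    df        p shapiro_W shapiro_p
#>   <chr>    <int>      <dbl>    <dbl> <dbl> <dbl>    <dbl>     <dbl>     <dbl>
#> 1 MAP          6       11.5     3.28  8.60     5 0.000351     0.991     0.993
#> 2 AoS          6       11.6     3.33  8.55     5 0.000360     0.959     0.814
#> 3 AoD          6       11.4     3.39  8.21     5 0.000437     0.979     0.944
```

The recovered group mean MAP delta (11.5 ± 3.3 mmHg) matches the injected
amplitudes (mean 11.5 mmHg): the normalization has removed the per-segment
baselines, and the paired t test across segments is strongly significant.
`plot_response_band(summarize_band(norm))` draws the mean ± SD band of the
normalized responses; `autoplot()` on the comparison gives the MAP-delta
histogram.

The packaged blood-chemistry panel reproduces the published group
summaries and the across-round decline in ionized calcium:

```r
library(dplyr)
c12 <- filter(load_chemistry(), cohort %in% 1:2)
aggregate_chemistry(c12)
#> # A tibble: 6 x 5
#>   group    analyte     n  mean     sd
#> 1 baseline pH         24  7.46 0.0724
#> 2 baseline iCa        24  1.28 0.0887
#> 3 round1   pH         20  7.33 0.105
#> 4 round1   iCa        20  1.23 0.0827
#> 5 other    pH         43  7.35 0.0898
#> 6 other    iCa        43  1.21 0.131
chemistry_anova(c12, "iCa")
#> # A tibble: 1 x 4
#>       F df_between df_within      p
#> 1  3.70          2        56 0.0309
```

Ionized calcium falls from 1.28 mmol/L at baseline to 1.23 after the first
injury round and 1.21 over later rounds (p = 0.03). `chemistry_report()`
flags the summary cells that do not survive recomputation from the
per-animal panel rather than matching them.

A thin CLI over the same functions lives at `inst/scripts/capressor`
(`simulate`, `analyze`, `chemistry` subcommands).

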