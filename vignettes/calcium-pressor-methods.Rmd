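---
title: "Methods: quantifying calcium pressor responses beat by beat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying calcium pressor responses beat by beat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capressor)
library(dplyr)
```

## The problem

After resuscitation from pseudo-pulseless electrical activity (pseudo-PEA —
profound cardiac shock with measurable mechanical activity but no clinically
detectable pulse), animals are often left hypotensive and refractory to
catecholamine pressors. Boluses of intravenous calcium given in this state
can produce a pressor response: a rise in arterial pressure that is well
approximated by a logistic (sigmoid) curve in time. Quantifying that
response from continuous arterial pressure recordings is harder than it
sounds, because the post-resuscitation baseline is unstable — drifting,
heterogeneous across animals, and overlaid with a ventilation artifact —
so raw pressures cannot simply be averaged across boluses.

`capressor` implements the full analysis chain:

1. **Beat detection** on the aortic pressure waveform and per-beat
   hemodynamics: mean (`MAP`), systolic (`AoS`) and diastolic (`AoD`)
   aortic pressure, plus coronary (`CPP`) and cerebral (`CePP`) perfusion
   pressure when right-atrial and intracranial channels are present.
2. **Segmentation**: each calcium bolus claims the interval reaching
   half-way to the neighbouring injection of any drug, isolating its effect.
3. **Midpoint detection**: the inflection of the sigmoid response is located
   at a zero-crossing of the second derivative of smoothed beat-level
   pressure series.
4. **Normalization**: time and pressure are re-expressed so the midpoint
   sits at (t = 0, ΔP = 0), making heterogeneous responses comparable.
5. **Comparison**: pressures averaged over the 4-s windows (−40, −36) and
   (36, 40) around the midpoint are compared with a paired t test.
6. **Chemistry**: longitudinal blood-gas panels (pH, ionized calcium) are
   aggregated by experimental round and compared with one-way ANOVA.

Because the original raw recordings are not publicly deposited, the package
ships a ground-truthed synthetic generator that reproduces the statistical
structure the analysis must cope with; every stage is validated against
generator truth.

## The synthetic generator: what it emulates, and what it does not

`simulate_recording()` composes the aortic channel additively:

* a **pulsatile beat train** — by default an asymmetric pulse (fast
  systolic upstroke over the first quarter of the cycle, exponential
  diastolic decay) so beat detection is exercised on realistic morphology;
  a pure-sinusoid mode is retained for analytic checks. The per-beat mean
  equals `baseline_map_mmHg` and peak-to-trough equals
  `pulse_pressure_mmHg` exactly;
* a **baseline trend** (linear slope, or saturating exponential), emulating
  post-resuscitation instability and decompensation;
* a **ventilation artifact**, a sinusoid at 0.25 Hz and 3 mmHg by default;
* the **logistic pressor response** of each bolus,
  `A / (1 + exp(-k (t - t0)))`, with known annotation time, midpoint `t0`,
  amplitude `A` and rate `k`;
* white Gaussian **measurement noise**.

Default conditions emulate a hypotensive ~30 kg swine shortly after return
of spontaneous circulation: 1000 Hz sampling, 90 bpm, MAP ≈ 55 mmHg with a
30 mmHg pulse pressure (systolic in the 70s — above the ≤ 50 mmHg systolic
shock threshold, below full recovery), 1 mmHg noise. The noise and artifact
amplitudes are stated in the configuration, not hard-coded, because the
source system's spectra were never characterized; the 2 mmHg noise used in
the validation studies is deliberately pessimistic for a modern pressure
catheter.

Right-atrial and intracranial channels are generated as low-amplitude,
offset copies of the same beat clock — enough to compute `CPP` and `CePP`,
with no independent physiology. The generator deliberately omits: heart-rate
variability and arrhythmia, reflected-wave morphology changes, chest
compressions, ECG morphology, and any closed-loop coupling between pressure
and the drugs. Passing the validation studies therefore demonstrates that
the *pipeline* recovers what it claims under realistic noise, drift and
artifact — not that it is robust to arrhythmia or sensor failure modes the
generator does not produce.

## Beat detection and per-beat conventions

Detection runs on a band-limited copy: a ~50 ms running mean suppresses
noise, a ~2 s running mean estimates baseline, and their difference
oscillates at the heart rate. Prominence-filtered local maxima (height floor
at 30% of the 98th percentile, minimum separation 250 ms) mark systolic
peaks; beat boundaries sit at the minimum between consecutive peaks — the
pre-upstroke diastolic trough. Beats shorter than 250 ms or longer than 2 s
(outside the physiologic range for a juvenile pig) are dropped. Signals
whose band-limited excursion stays below 5 mmHg are declared pulseless and
return an empty beat table with a warning rather than an error, since a
pulseless stretch is a physiological outcome, not a data defect.

Summaries always use the **raw** samples within each beat: `AoS` is the
maximum, `AoD` the minimum, and `MAP` the arithmetic mean of all samples —
the true waveform mean, not the `(2·AoD + AoS)/3` cuff approximation, since
the full waveform is available. `CPP` = `AoD` minus the right-atrial
pressure at the instant of the diastolic minimum; `CePP` = `MAP` minus the
mean intracranial pressure over the beat. These are the standard
resuscitation-literature conventions; the original analysis scripts'
exact formulas are not recoverable, so the convention is stated rather than
inherited.

## Midpoint detection: the decisions that were genuinely open

The midpoint is located at a zero-crossing of the second derivative of a
smoothed beat-level series, computed for `AoS`, `CPP` and `CePP` and
reconciled across signals. Several choices are under-determined by that
one-sentence description; the package fixes them as follows, each exposed in
`smoothing_config()`:

* **Smoothing before differentiation is mandatory.** A beat-level series
  carries the ventilation artifact at nearly full amplitude; its second
  derivative (amplitude × ω² ≈ 7 mmHg/s² at 3 mmHg, 0.25 Hz) dwarfs the
  curvature of the response itself (≈ 0.02–0.3 mmHg/s² for amplitudes
  5–15 mmHg at rates 0.2–0.5 /s). The detection smoother is a centered
  moving average of `detection_window_beats = 15` beats applied
  `detection_passes = 3` times; repeated passes approximate a Gaussian
  kernel of the same width, whose spectral tails fall much faster than a
  single boxcar's, which is what makes the weakest (5 mmHg, 0.2 /s)
  responses detectable above the crossing gate without destroying the
  fastest ones. The second derivative itself is smoothed once more before
  crossing detection (`smooth_d2 = TRUE`).
* **Derivatives on uneven beat times.** Three-point Lagrange central
  differences, exact for quadratics at any spacing; series endpoints are
  undefined (`NA`).
* **Crossing gate.** A sign change counts only when the second derivative
  reaches beyond ±`epsilon_mmHg_s2` (default 0.01 mmHg/s²) on both sides,
  suppressing numerical chatter; a flat segment therefore yields
  `valid = FALSE` — a value, not an exception.
* **Multiple crossings.** The crossing that mediates the largest curvature
  swing wins — measured as the integral of |d²P/dt²| over the two
  sign-runs it separates, i.e. the net slope change that curvature reversal
  accounts for. For a logistic response this is the crossing at the
  inflection; for artifact wiggles it is small.
* **Search window.** Crossings are searched in
  `(t_bolus, t_bolus + max_latency_s]` with a 30 s default: an intravenous
  bolus acts within tens of seconds, and bounding the search stops late
  artifact crossings from competing.
* **Consensus.** The median of the per-signal crossings — robust to one
  outlier signal, and degrading gracefully to `AoS` alone when perfusion
  channels are absent.

## Normalization and comparison

Normalized time is beat time minus midpoint time; normalized pressures
subtract the value at the **beat nearest t = 0** — not an interpolated
value — so the zero-at-midpoint anchor is exact to machine precision, and
the across-segment mean and SD at t = 0 are identically zero by
construction. The anchor beat's raw value carries whatever ventilation-phase
offset it happens to have, but this cancels in the before/after delta
(both windows shift by the same constant).

Comparison windows default to the open intervals (−40, −36) and (36, 40)
normalized seconds, averaged per segment and compared across segments with
a two-sided paired t test (`df = n − 1`), with Shapiro–Wilk normality
checks on the deltas. A segment whose window contains no beats — possible
when the midpoint falls late in a minimally-sized segment — is excluded
with a warning. The 40 s minimum context for a usable segment is an explicit
filter with provenance, not a silent drop: unusable segments are retained
with `usable = FALSE`. Segments are delimited by injections of *all* drug
types (calcium, epinephrine, bicarbonate), the inclusive reading of
isolation half-way between injections.

Response classification operationalizes "manifested a change" as midpoint
validity: `responder` = detectable sigmoid with positive MAP delta,
`negative_delta` = detectable sigmoid whose windowed delta is nonetheless
negative (decompensation outpacing the pressor effect), `no_effect` = no
detectable sigmoid. This is one defensible reading — the counts it produces
measure detectability and direction separately — and it is recorded in the
output metadata of every run.

No multiple-testing correction is applied across the three pressures, and
repeated boluses within one animal are treated as independent; both mirror
the study design this pipeline reproduces rather than improving on it.

## Blood chemistry

The packaged fixture transcribes the three-cohort per-animal panel (87
cohort-1/2 records, 61 cohort-3 records). Aggregation pools baseline,
round-1, and rounds ≥ 2 ("other rounds"), using the sample (n − 1) SD.
Recomputation reproduces the published baseline and round-1 cells at their
printed two-decimal rounding; the pooled rounds-2+ cells do **not**
reproduce (iCa recomputes to 1.21 against a printed 1.19), and
`chemistry_report()` flags such cells against the packaged reference
summary instead of matching them.

For the across-round ANOVA, `chemistry_anova()` defaults to averaging the
rounds-≥ 2 values **within each animal** before testing ("average remaining
rounds"), so each animal contributes one value to that group; with this
grouping the iCa decline across rounds tests at p ≈ 0.03 on the packaged
panel, whereas pooling every round-2+ record individually (available via
`rounds2plus = "pooled"`) dilutes the test with within-animal repetition
and gives p ≈ 0.05. The per-animal default is both the stated aggregation
of the source analysis and the statistically cleaner choice, since repeated
rounds within an animal are not independent.

One transcribed cell (cohort 1, animal 6, round 5: iCa 1.72 mmol/L) is
physiologically implausible and flagged `suspect = TRUE`, but retained in
all computations; several cohort-3 cells whose printed source was ambiguous
are flagged the same way. Cohort-3 summaries are provided but never
asserted as reproduction targets, because the printed record does not
unambiguously identify the calcium-treated subset.

## Validation studies and problem sizes

Three seeded studies, all runnable from the installed package, back the
pipeline's claims (`midpoint_recovery_study()`, `effect_recovery_study()`,
`t_test_type1_study()`):

* **Midpoint recovery** — 100 single-bolus segments (120 s at 1000 Hz)
  cycling amplitudes {5, 10, 15} mmHg × rates {0.2, 0.5} /s under 2 mmHg
  noise and the default ventilation artifact, checked for median absolute
  error ≤ 2 s and ≥ 90% of cases within 3 s.
* **Effect-size recovery** — 50 replicate cohorts of 37 boluses with
  amplitudes drawn from N(12, 6²) mmHg, each bolus simulated and analyzed
  end-to-end, checked for the group-mean MAP delta landing within 1.5 mmHg
  of the injected mean. Boluses whose response is too small to detect are
  excluded by the pipeline itself, exactly as undetectable responses would
  be in practice.
* **Type-I error** — 2000 null replicates of 34 paired differences,
  checked against the [0.035, 0.065] band around the nominal 0.05.

These sizes keep the full validation suite to a few minutes on a single
core while leaving the Monte-Carlo bands comfortably wider than the
sampling error at those replicate counts.

## Known limitations

* Pressure-only beat detection: no ECG gating, no arrhythmia handling.
* The midpoint search assumes one dominant response per segment; overlapping
  pharmacology inside a segment is out of scope (segmentation is the
  defense, not deconvolution).
* The generator's beat clock is metronomic; beat-time unevenness in real
  data is handled by the uneven-spacing derivative but not stress-tested
  beyond it.
* Cohort-3 chemistry transcription is best-effort with flagged ambiguities;
  its injection counts should not be treated as exact.
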