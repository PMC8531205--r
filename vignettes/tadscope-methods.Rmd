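---
title: "Methods: thermal-physiology pipelines in tadscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermal-physiology pipelines in tadscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tadscope)
```

tadscope turns four kinds of raw recordings from a tadpole
thermal-acclimation experiment into physiological summaries: oxygen
consumption rates from intermittent-flow respirometry, heart rates and
autonomic tones from electrode recordings, critical thermal maxima from
heating ramps, and daily/seasonal statistics from microhabitat temperature
loggers. A synthetic-data module generates each raw input type with known
ground truth, so the whole chain is testable by parameter recovery. This
vignette documents the models, the tunable parameters and the numerical
choices.

## Respirometry

Intermittent-flow respirometry alternates *flush* phases (chamber open,
water exchanged) with *sealed* phases in which the animal draws down the
oxygen in a closed chamber. The analysis chain is:

1. **Saturation to concentration.** Optode sensors report percent air
   saturation; the metabolic-rate equation needs µmol O~2~ L^-1^. The
   bridge is the Benson–Krause solubility formulation used in the standard
   USGS/APHA dissolved-oxygen tables (`o2_solubility_umol_l()`), with
   temperature, barometric pressure and salinity arguments. Defaults are
   sea-level pressure and fresh water. The test suite pins the model to the
   published table (8.263 mg L^-1^ at 25&nbsp;°C and 760 mmHg ≈ 258 µmol
   L^-1^). Barometric pressure at the originating lab's altitude is not
   documented, so pressure is an explicit argument with a sea-level
   default; at ~600 m the correction is about −7%, applied identically to
   generation and analysis so recovery tests are unaffected.
2. **Segmentation.** `segment_cycles()` extracts the contiguous sealed
   segments and trims a 60 s leading dead time (configurable) to discard
   mixing transients after sealing.
3. **Slope fitting.** `fit_slope()` regresses concentration on time (h) by
   ordinary least squares. For a flat (zero-variance) response r² is
   defined as 0: a flat trace carries no rate information and this
   definition forces the QC stage to reject it.
4. **Quality control.** `qc_filter()` passes a slope iff r² ≥ 0.95 *and*
   the segment's minimum saturation stayed at or above 80%. Both
   boundaries are inclusive (a slope at exactly r² = 0.95 or a minimum of
   exactly 80.0% passes). Rejections carry machine-readable reasons
   (`low_r2`, `sat_floor`) and are counted in the study manifest, so QC
   data loss is auditable.
5. **The metabolic-rate equation.** `compute_mo2()` computes total
   consumption as |slope| × V~RE~ − background, where the effective volume
   V~RE~ = (chamber volume − organism volume) uses organism density 1 kg
   L^-1^ (so a 1.3 g animal displaces 1.3 mL of a 43 mL chamber). The
   mass-specific rate divides by wet mass. A negative post-background rate
   is flagged, never clipped: it indicates a calibration problem the user
   must see.
6. **Duplicates.** Each animal × temperature condition is measured in
   duplicate sealed cycles; `summarize_duplicates()` averages the QC
   survivors and records how many contributed. When both duplicates fail,
   a missing-value record with the rejection reasons is returned. Whether
   the original design averaged duplicates or modelled them as repeated
   measures is not documented; averaging is the default here and the tidy
   per-cycle table remains available for mixed-model work.

**Background respiration** is measured from empty-chamber control traces
through the same segmentation and slope machinery
(`measure_background()`), per test temperature, and subtracted as an
absolute µmol h^-1^ rate. The r² criterion is deliberately *not* applied
to controls: a control trace with a near-zero decline legitimately has low
explanatory power, and rejecting it would silently zero the correction.

**Seal duration.** The synthetic protocol sizes sealed phases with
`auto_seal_min()`, which spends ~85% of the saturation budget between 100%
and the 80% floor. Using most of the budget keeps the decline large
relative to sensor noise — at 1% saturation noise the expected r² scales
as D²/(D² + 12σ²) for a decline of D percentage points, so D ≈ 17 gives
r² ≈ 0.96 — while the remaining headroom stops noise from dragging the
measured minimum below the floor.

## Heart rate and autonomic tones

Electrode recordings (1 kHz) are low-pass filtered at 50 Hz with a
4th-order zero-phase Butterworth (`filter_signal()`), then beats are
detected by an amplitude threshold with a 0.2 s refractory period
(`detect_beats()`). Because electrode amplitude scales are arbitrary, the
threshold self-calibrates at 5 × MAD above the median; for noiseless
sparse spike trains (where the MAD collapses to zero) it falls back to
half the peak amplitude. The 0.2 s refractory period corresponds to a
300 bpm ceiling, far above observed tadpole rates (~50–100 bpm).

`mean_fh()` operationalizes "a visibly stable 5-minute stretch"
reproducibly: it scans contiguous 5-min windows at 1 s stride and selects
the one with minimum inter-beat-interval coefficient of variation,
flagging the result if that CV exceeds 0.25.

`autonomic_tones()` expresses cardiac autonomic control relative to the
intrinsic rate, taken as the double-blockade (atropine + sotalol) rate:

- cholinergic tone (%) = 100 × (f~H,atropine~ − f~H,routine~) / f~H,double~
- adrenergic tone (%) = 100 × (f~H,atropine~ − f~H,double~) / f~H,double~

These follow the standard comparative-physiology convention; negative
tones are reported with a flag rather than suppressed. The identity
cholinergic − adrenergic = 100 × (f~H,double~ − f~H,routine~) / f~H,double~
is enforced by tests.

## Thermal tolerance

CTmax trials ramp temperature at a nominal 0.1&nbsp;°C min^-1^ until a
behavioural endpoint (loss of escape response). The endpoint is an
observational annotation — it cannot be inferred from the temperature
channel — so `extract_ctmax()` requires it and reads the (optionally 5 s
median-smoothed) temperature at that moment. The realized heating rate is
the OLS slope of temperature on time from start to endpoint
(`estimate_heating_rate()`); realized slopes in the source protocol were
0.089–0.091&nbsp;°C min^-1^, slightly below nominal, and the synthetic
defaults reproduce that. Warming tolerance is the plain difference
WT = CTmax − T~max,habitat~, with T~max,habitat~ conventionally the
wet-season mean daily maximum from the habitat module; a negative WT is
returned with a warning.

## Habitat summaries

`daily_stats()` groups hourly logger samples by calendar date (days with
fewer than 20 of 24 samples are flagged); `period_summary()` filters to a
month window that may wrap the year end (October→May by default,
reflecting the months with water in the stream) and reports means ± sd
(and s.e.m. — the dispersion label is explicit because a bare "±" is
ambiguous). `temp_histogram()` builds the frequency histogram on 0.5 °C
bins *centered* on multiples of 0.5 (edges at 0.25 offsets), left-closed
right-open; "bin centered at 0.5 degree interval" admits two readings and
this package adopts the half-degree-centers one, with the width exposed
as an argument.

## Aerobic scope and thermal performance

`build_scope_curve()` computes absolute scope AAS = mMO~2~ − rMO~2~ and
factorial scope FAS = mMO~2~ / rMO~2~ on group means per test temperature
— on means, because routine and maximum rates come from different animals
in the underlying design. Missing rates yield missing scope; FAS is
undefined (missing) where rMO~2~ = 0.

`fit_gaussian_tpc()` fits a · exp(−(T − µ)² / 2σ²) by Levenberg–Marquardt
least squares with multiple starts of µ over the test-temperature grid,
keeping the best residual sum of squares. The 3-parameter form (no
baseline) is the default, with a baseline offset opt-in, since the curve
family alone is documented for the source analysis. Monotone data pin µ̂ at
the edge of its box (±10 °C beyond the tested range) and set a `boundary`
flag; non-convergence returns `converged = FALSE` with the best-found
parameters rather than an error.

`q10()` is (R₂/R₁)^(10/(T₂−T₁)); multiplicativity over composed
temperature spans is a tested invariant.

## The synthetic-data module

Each generator draws from one seeded stream per call, so identical seed +
parameters give byte-identical output, and stores its ground truth in the
returned object:

- `gen_o2_trace()` — linear sealed-phase declines at the rate implied by
  (mass-specific rate × mass + background) / V~RE~, converted to percent
  through the same solubility model the analysis uses; exponential flush
  recovery with a 30 s time constant (plumbing realism; unconstrained by
  the source protocol); Gaussian noise on the saturation channel, the
  sensor's native unit. Parameter sets that would cross the saturation
  floor are rejected at generation time, naming the cycle.
- `gen_heart_signal()` — beat intervals 60/f~H~ × (1 + cv·ε), a 40 ms
  raised-cosine pulse per beat (simple, band-limited, detection-friendly;
  the real electrode waveshape is not documented), additive noise.
- `gen_ctmax_ramp()` — linear ramp plus sensor noise, endpoint annotated
  at the first sample whose noiseless temperature reaches the true CTmax.
- `gen_habitat_series()` — seasonal sinusoid (warmest mid-January,
  southern hemisphere) + diel sinusoid (warmest 15:00, on-sample so daily
  extremes are exact at zero noise) + noise.

**Condition defaults are the study's printed group means.**
`condition_defaults()`, `heart_rate_defaults()`, `ctmax_defaults()` and
`cohort_defaults()` transcribe the published group-level results (e.g.
routine MO~2~ 15.95 µmol g^-1^ h^-1^ for the warm-acclimated group at
30 °C; routine f~H~ 52.07 bpm at 18 °C; CTmax 36.8 ± 0.2 °C). Conditions
the source never printed are filled on a log-linear temperature curve —
interpolation between printed anchors where they bracket the temperature,
otherwise Q10 = 2 extrapolation from the nearest anchor — and carry
`source = "interpolated"` so they are never mistaken for empirical values.
The maximum-rate curve for the warm-acclimated group has no printed means
at all; it is set to 75% of the cold-acclimated curve, matching the
qualitative report that it stayed below it throughout.

**Between-animal variance** is not recoverable from published group
summaries, so it is a free parameter: cohort generators take an explicit
sd (the worked examples use s.e.m. × √n from the published tables), heart
recordings take a beat-interval CV (default 0.05), and CTmax endpoints are
drawn per animal. Habitat defaults (annual mean 21.3 °C, diel
half-amplitude 2.9 °C, seasonal half-amplitude 1.5 °C, sensor noise
0.2 °C) were chosen once so that the October–May window statistics land on
the published wet-season values (mean ≈ 21.9 °C, mean daily extremes
≈ 18.8 / 24.6 °C); the seasonal half-amplitude and noise level are realism
choices, not measurements.

**What the generator does not emulate:** animal activity and behavioural
state changes (so "routine" vs "maximum" differ only in their true rate),
optode drift and calibration error, movement artifacts in electrode
recordings beyond stationary Gaussian noise, and logger emersion during
dry season. Passing recovery tests therefore demonstrates that the
analysis chain is correct and unbiased under the stated noise model — not
that it is robust to every artifact of real recordings.

## Problem sizes and reproducibility

The shipped tests and the acceptance script run at the study's own scale:
8 animals per respirometry group with duplicate cycles at 0.2 Hz, 6-minute
1 kHz electrode recordings, 7 CTmax ramps of ~190 min at 1 Hz, and a year
of hourly logging. Monte-Carlo checks use 100 replicates. `run_study()`
derives all per-task seeds deterministically from one base seed and writes
a manifest (package version, thresholds, QC rejection counts, output
checksums), so a rerun with the same configuration is byte-identical.

## Known limitations

- The solubility model is a freshwater formulation; brackish field sites
  would need the salinity argument and validation beyond the 0–45 °C range
  used here.
- Scope on group means propagates no uncertainty; confidence intervals on
  AAS/FAS would need per-animal designs or resampling.
- The Gaussian TPC is a descriptive fit, deliberately not a mechanistic
  (e.g. Sharpe–Schoolfield) model; its optimum is only meaningful within
  the tested temperature range, and the `boundary` flag must be checked.
- Inferential modelling (mixed models, post-hoc contrasts) is out of
  scope: the package emits tidy per-animal tables ready for `nlme`/`lme4`.
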