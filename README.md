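# tadscope

Analysis pipelines for comparative thermal ecophysiology of small aquatic
ectotherms — built around the measurement chain of a tadpole
thermal-acclimation experiment, and useful wherever the same instruments
are used:

- **Respirometry** — intermittent-flow % air-saturation traces →
  quality-controlled routine and maximum metabolic rates. Saturation is
  converted to µmol O₂ L⁻¹ through the Benson–Krause freshwater solubility
  model, sealed-phase declines are fitted by OLS, slopes are kept only if
  r² ≥ 0.95 and saturation stayed ≥ 80%, and rates follow the
  effective-volume equation MO₂ = V_RE · W₀⁻¹ · |dC_O₂/dτ| with
  V_RE = chamber volume − organism volume (density 1 kg L⁻¹), minus an
  empty-chamber background rate.
- **Cardiovascular** — raw 1 kHz electrode recordings → heart rate over
  the most stable 5-min window (zero-phase 50 Hz low-pass, MAD-threshold
  beat detection with a 0.2 s refractory period), and partitioning of
  cholinergic/adrenergic tones from atropine / atropine+sotalol blockade,
  relative to the intrinsic (double-blockade) rate.
- **Thermal tolerance** — 0.1 °C min⁻¹ heating ramps with an annotated
  behavioural endpoint → CTmax, realized heating rate, and warming
  tolerance WT = CTmax − T_max,habitat.
- **Habitat** — hourly temperature-logger series → daily min/max/mean,
  wrap-aware wet-season (October–May) summaries, and frequency histograms
  on 0.5 °C-centered bins.
- **Scope** — absolute (mMO₂ − rMO₂) and factorial (mMO₂ / rMO₂) aerobic
  scope on group means, Gaussian thermal performance curve fits
  a·exp(−(T−µ)²/2σ²) with multi-start nonlinear least squares, and Q10
  temperature coefficients (R₂/R₁)^(10/(T₂−T₁)).
- **Synthetic data** — generators for every raw input type with known
  ground truth (default parameters transcribed from the source study's
  printed group means), so each pipeline stage has a parameter-recovery
  test surface.

## Worked example

```r
library(tadscope)

# one warm-acclimated animal at 30 degC: duplicate sealed cycles, 0.5%
# sensor noise, background respiration in the chamber
tr <- gen_o2_trace(true_mo2_umol_g_h = 15.95, mass_g = 0.7, chamber_ml = 43,
                   temp_C = 30, n_cycles = 2, seal_min = 8,
                   noise_sd_pct = 0.5, background_umol_h = 0.3, seed = 42)
ctrl <- gen_o2_trace(0, mass_g = 1e-3, chamber_ml = 43, temp_C = 30,
                     n_cycles = 2, seal_min = 12, noise_sd_pct = 0.5,
                     background_umol_h = 0.3, seed = 43)
mo2_from_trace(tr, background_umol_h = measure_background(ctrl))
#> $mo2_total_umol_h
#> [1] 11.06262
#> $mo2_mass_specific_umol_g_h
#> [1] 15.80374
#> $n_used
#> [1] 2
#> ...
```

The recovered mass-specific rate (15.80 µmol O₂ g⁻¹ h⁻¹) matches the
generator's ground truth (15.95) to within 1% at this noise level: both
duplicate cycles passed QC and the measured background was subtracted
before mass normalization.

```r
# heart rate and autonomic tones at 25 degC
rates <- sapply(c(routine = 80.3, atropine = 98.1, double = 85.5),
                function(f) fh_from_recording(
                  gen_heart_signal(f, duration_s = 360, seed = 7))$fh_bpm)
round(rates, 1)
#>  routine atropine   double
#>     80.2     98.0     85.4
autonomic_tones(rates[1], rates[2], rates[3])[c("cholinergic_pct",
                                                "adrenergic_pct")]
#> $cholinergic_pct
#> [1] 20.85932
#> $adrenergic_pct
#> [1] 14.78487
```

Atropine raises the rate by ~21% of intrinsic (cholinergic tone) and the
double blockade sits ~15% below the atropine rate (adrenergic tone): the
two autonomic limbs pull on the heart with nearly equal strength.

```r
q10(52.07, 80.3, 18, 25)$q10   # heart-rate thermal sensitivity
#> [1] 1.856753  (~1.9: rate nearly doubles per 10 degC)
warming_tolerance(36.8, 24.6)  # CTmax minus wet-season daily maximum
#> [1] 12.2
```

`run_study()` chains everything — synthetic generation → all pipelines →
tidy CSVs plus a JSON manifest with seeds, QC-rejection counts and output
checksums — and reruns byte-identically under the same configuration.

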