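# stpdosim

Single-time-point (STP) versus multiple-time-point (MTP) image-based
dosimetry for Lu-177 PSMA radioligand therapy.

Routine dosimetry for radiopharmaceutical therapy needs the
time-integrated activity (TIA) of each volume of interest (VOI) — kidneys,
individual lesions, whole-field tumor burden — which classically requires
SPECT imaging at several time points per cycle (~24, 48, 72 h post
injection). This package is for medical-physics and nuclear-medicine
researchers evaluating whether a *single* scan per cycle can replace the
full schedule. It implements:

* monoexponential time–activity fitting per VOI
  (`fit_monoexponential()`): log-linear ordinary least squares for
  `A(t) = A0 · 2^(−t/T½eff)`, with the MTP reference TIA
  `TIA_ref = A0 · T½eff / ln 2` (`tia_reference()`);
* two STP estimators: the prior-information method
  `TIA = A(t) · 2^(t/T_prior) · T_prior / ln 2` (`stp_prior()`, reusing the
  first cycle's fitted half-life) and the Hänscheid approximation
  `TIA ≈ A(t) · 2t / ln 2` (`stp_hanscheid()`), plus the closed-form error
  structure of the latter, `e(x) = 2x·2^(−x) − 1` with `x = t/T½eff`
  (`stp_h_relative_error()`), and its 0.75–2.5 × T½eff validity window;
* cohort-level comparison statistics (`compare_cohort()` and friends):
  percentage differences versus the MTP reference, Bland–Altman summaries,
  exact tie-aware Wilcoxon signed-rank tests, ±10%/±20% coverage tables,
  validity-window coverage tables, inter-cycle half-life change counts;
* a seeded synthetic cohort generator (`generate_cohort()`) calibrated to
  published Lu-177-PSMA-617 population kinetics (truncated-normal
  half-life distributions per VOI type and cycle, correlated across cycles,
  multiplicative lognormal measurement noise, jittered schedules), and a
  voxel-phantom path (`build_phantom()`, `segment_fixed_threshold()`,
  `concentration_to_suv()`) exercising threshold segmentation and SUV
  conversion with NIfTI I/O;
* a one-call pipeline (`run_pipeline()`) writing a reproducible report
  bundle (fit, PD, Bland–Altman, coverage, window and Wilcoxon tables plus
  a JSON manifest).

## Worked example

```r
library(stpdosim)

## one kidney, second cycle, three scans
cv <- tac("P001", 2, "kidney_left", "kidney_left",
          time_h = c(24, 48, 72), activity_MBq = c(59.94, 35.92, 21.53))
f <- fit_monoexponential(cv)
f
#> <monoexp_fit> P001 cycle 2 kidney_left: A0 = 100 MBq, T1/2eff = 32.49 h
#>   (n = 3, RMS log resid = 4.78e-05)
tia_reference(f)
#> <tia_estimate> MTP_ref: 4688.4 MBq.h (all time points)
stp_hanscheid(35.92, 48)
#> <tia_estimate> STP_H: 4974.9 MBq.h (t = 48 h)
stp_prior(35.92, 48, prior_half_life_h = 30.1)
#> <tia_estimate> STP_prior: 4711.1 MBq.h (t = 48 h)
```

The fit recovers the generating curve (A0 = 100 MBq, T½eff ≈ 32.5 h). The
single-scan Hänscheid estimate at 48 h is +6.1% above the MTP reference —
exactly `stp_h_relative_error(48 / 32.49)`, since 48 h is near the
worst-case ratio 1/ln 2 ≈ 1.44 half-lives — while the prior-information
estimate with a slightly wrong prior (30.1 h vs 32.49 h) lands within
+0.5%.

At cohort scale:

```r
co  <- generate_cohort(cohort_params(n_patients = 20, seed = 1))
rec <- compare_cohort(co)        # STP vs MTP for every VOI x time x method
head(coverage_table(rec), 4)
#>      voi_type    method nominal_time_h  n frac_within_10 frac_within_20
#> 1 kidney_left     STP_H             24 20           0.65           0.85
#> 2 kidney_left     STP_H             48 20           0.95           1.00
#> 3 kidney_left     STP_H             72 20           0.60           0.85
#> 4 kidney_left STP_prior             24 20           0.70           0.90
```

Read: with a single 48 h scan, the Hänscheid estimator put 95% of left
kidneys within ±10% of the full MTP reference on this simulated cohort —
the 48 h scan sits inside the 0.75–2.5 half-life validity window for
essentially all kidneys, whereas a 24 h scan does not.

The methods vignette (`vignettes/stp-dosimetry.Rmd`) documents the models,
the calibration of the simulator, and every numerically consequential
design choice.

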