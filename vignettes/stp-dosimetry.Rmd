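---
title: "Single-time-point dosimetry: models, estimators and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-time-point dosimetry: models, estimators and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stpdosim)
```

## The problem

Internal dosimetry for Lu-177 radioligand therapy needs the time-integrated
activity (TIA) of each volume of interest (VOI) — kidneys, individual
lesions, and a whole-field-of-view tumor-burden region (TB_FOV). The
reference procedure images the patient at multiple time points (MTP,
typically ~24, 48 and 72 h post injection), fits a washout model, and
integrates it. Because MTP imaging is a major practical burden, two
single-time-point (STP) shortcuts are of interest for the second and later
therapy cycles:

* **STP_prior** — reuse the effective half-life fitted during the first
  cycle together with one measured activity of the current cycle;
* **STP_H** (Hänscheid approximation) — estimate the TIA from one measured
  activity alone, with no half-life at all.

This package implements the full MTP-vs-STP comparison pipeline and a
synthetic cohort generator so the statistical machinery can be exercised,
tested and extended without access to patient data.

## Models and estimators

**Washout model.** Each VOI's curve is modelled as a monoexponential,
$A(t) = A_0 \, 2^{-t/T_{1/2,\mathrm{eff}}}$, where $T_{1/2,\mathrm{eff}}$
combines physical decay and biological clearance. `fit_monoexponential()`
performs unweighted ordinary least squares on $\ln A$ versus $t$. This
objective was chosen because it is exactly solvable (no starting values, no
convergence failures, reproducible across platforms) and corresponds to a
multiplicative error model, which matches how quantitative SPECT activity
errors behave. With exactly two samples it is the exact interpolant; the
number of points is recorded so degraded schedules can be filtered
downstream. A nonlinear least-squares fit on the linear scale would differ
only at second order at the ~5% noise levels considered here. Curves that
do not decay (fitted $\lambda_{\mathrm{eff}} \le 0$) are flagged rather than
silently clipped; TIA operations refuse them.

**Reference TIA.** `tia_reference()` integrates the fitted model
analytically: $\mathrm{TIA}_{\mathrm{ref}} = A_0 T_{1/2,\mathrm{eff}} /
\ln 2$.

**STP_prior.** `stp_prior()` back-decays the single measured activity to
$t = 0$ with the prior half-life and integrates:
$\mathrm{TIA} = A(t)\,2^{t/T_{\mathrm{prior}}}\, T_{\mathrm{prior}}/\ln 2$.
It takes the prior half-life as a plain argument rather than a cycle
object, so the same code serves the first-cycle prior (the default
pipeline) and population-prior variants.

**STP_H.** `stp_hanscheid()` computes $A(t)\cdot 2t/\ln 2$. Its relative
error against the exact TIA of a monoexponential curve depends *only* on
the ratio $x = t/T_{1/2,\mathrm{eff}}$:
$e(x) = 2x\,2^{-x} - 1$, exposed as `stp_h_relative_error()`. The error is
zero exactly at $x = 1$ and $x = 2$, peaks at $x = 1/\ln 2 \approx 1.44$
with $2/(e\ln 2) - 1 \approx +6.15\%$, and equals $-10.8\%$ and $-11.6\%$
at the conventional validity-window boundaries $x = 0.75$ and $x = 2.5$.
Note that these boundary magnitudes slightly exceed the often-quoted
"within 10%" heuristic for the window; the package documents the exact
values and does not enforce the heuristic. Window membership
(`in_hanscheid_window()`) treats the endpoints as inclusive, the
conservative choice for validity tallies, since the defining interval is
stated without openness.

## Comparison statistics

`compare_cohort()` fits the cycle-2 MTP reference per VOI, then evaluates
both STP estimators at each nominal time (default 24/48/72 h) using the
*measured* sample nearest the nominal time (tolerance ±6 h, accommodating
realistic scheduling jitter) — not a model prediction, because an STP
protocol would only ever see the raw measurement. Percentage difference is
always $100(\mathrm{STP} - \mathrm{ref})/\mathrm{ref}$.

Design choices that were genuinely open:

* **Bland–Altman denominator.** The difference axis uses the MTP reference
  as denominator, keeping a single difference definition across the PD
  analysis and the Bland–Altman summaries; the conventional pair-mean
  denominator is available via `denominator = "pair_mean"`. The
  limits-of-agreement multiplier is the standard 1.96.
* **Wilcoxon signed-rank.** Zero differences are dropped (classic
  treatment, not Pratt's), tied magnitudes get mid-ranks, and for up to 25
  usable pairs the two-sided p-value is exact, computed from the full null
  distribution of the statistic built by convolution over the (possibly
  tied) ranks. Beyond that a normal approximation with tie-corrected
  variance and continuity correction is used. No multiplicity correction is
  applied; raw p-values are reported.
* **Coverage bounds.** The ±10%/±20% coverage tables use inclusive bounds,
  whereas inter-cycle half-life changes are counted when *strictly* greater
  than ±20%, following the usual phrasing "more than ±20%".

## The synthetic cohort

`generate_cohort()` emulates the study design the statistics assume: 20
patients (default) × 2 cycles, two kidneys (15% of patients have a single
active kidney), 0–6 tracked lesions per patient, and a TB_FOV curve defined
as the sample-wise sum of the lesion curves (so activity is conserved by
construction, while the pipeline still fits TB_FOV independently, as a real
analysis would). All VOIs of a patient-cycle share one jittered scan
schedule, like a real scanning session.

Effective half-lives are drawn from truncated normal distributions on the
natural scale whose mean ± SD and (min; max) match published
Lu-177-PSMA-617 population values per VOI type and cycle — kidneys
32.5 ± 7.0 h (17.8; 51.9) in cycle 1 and 31.7 ± 6.4 h (21.6; 45.7) in
cycle 2; lesions 69.0 ± 40.0 h (20.1; 249.7) and 66.6 ± 34.2 h
(19.7; 216.2). The truncated normal was chosen over a lognormal because it
reproduces the printed moments and ranges directly. Cycles are coupled by a
Gaussian copula: one latent standard normal per VOI and cycle with
correlation $\rho$ between cycles, mapped through the exact truncated-normal
quantile function, so the per-cycle marginals are exact regardless of
$\rho$. The default $\rho = 0.8$ was calibrated once, before any
acceptance run, so that ≈46% of lesions change their half-life by more
than ±20% between cycles (the observed clinical fraction, 26 of 56); the
calibration gives 47.1% at $\rho = 0.8$ over $2\times10^6$ draws.

Measurement noise is multiplicative lognormal with coefficient of variation
`noise_cv` (default 0.05, typical of quantitative Lu-177 SPECT) and unit
mean on the linear scale ($\epsilon \sim N(-\sigma^2/2, \sigma)$,
$\sigma = \sqrt{\log(1+\mathrm{cv}^2)}$). Amplitudes $A_0$ are the injected
activity (truncated normal, 6090 ± 130 MBq on (5740; 6700)) times a
lognormal per-VOI uptake fraction (kidney median 2%, lesion median 0.5%).
No per-VOI uptake data are published, so these magnitudes are simulator
choices; only relative quantities (percentage differences) are meaningful
downstream, and the tests only assert relative behavior. An optional slow
second exponential (`second_component`) produces biexponential truth while
the analysis remains monoexponential, for robustness studies.

What the simulator does *not* model: SPECT acquisition and reconstruction,
partial-volume and scatter effects, registration error between time points,
and progressive anatomical change. Passing tests on this cohort therefore
demonstrate the correctness and calibration of the estimators and
statistics, not the clinical accuracy of STP dosimetry on real images.

## The phantom path

For the segmentation stage, `phantom_spec()`/`build_phantom()` create 3-D
voxel grids with spherical or ellipsoidal objects that decay with per-object
half-lives, readable and writable as NIfTI. `segment_fixed_threshold()`
applies the fixed-threshold rule used for kidney VOIs (default 20% of the
regional maximum) and keeps the 26-connected component containing the
maximum voxel; 26-connectivity is fixed because the original segmentation
was done in external software that does not document its choice, and the
most permissive neighborhood is the conservative one for threshold VOIs.
The full iterative SUV-threshold lesion algorithm used clinically is out of
scope; `concentration_to_suv()` provides the body-weight SUV conversion a
configurable cutoff would operate on. Object voxelization is by
center-inclusion, which overestimates a radius-3 sphere's volume by ~8%;
tests therefore compare recovered activity against the analytic volume with
discretization-aware tolerances.

## Numerical choices and degenerate inputs

* All computations in MBq and hours; TIA in MBq·h.
* Flat or rising curves: flagged non-decaying; `tia_reference()` errors,
  `compare_cohort()` skips them with a warning.
* A nominal STP time with no sample within ±6 h: skipped with a warning.
* VOIs without a cycle-1 counterpart: contribute Hänscheid records only
  (with a warning), mirroring the restriction to lesions visible in both
  cycles.
* All randomness flows from a single integer seed; a cohort, and the whole
  report bundle of `run_pipeline()`, are byte-reproducible functions of the
  configuration (timestamps appear only in the run manifest).

## Problem sizes used in the tests

The test suite fits ~1000 noisy three-point curves for the
parameter-recovery property, uses a 200-patient synthetic cohort for the
cohort-structure checks, $10^4$ replicates for the noise-model check, and
$32^3$ phantom grids — sizes chosen so each property is measured with
comfortable statistical margin while the whole suite stays fast on one CPU.

## Worked example

```{r}
co <- generate_cohort(cohort_params(n_patients = 20, seed = 1))
rec <- suppressWarnings(compare_cohort(co))
head(coverage_table(rec))
```

```{r}
fits <- fit_cohort(co)
head(window_coverage_table(fits))
```

## Known limitations

* The monoexponential model ignores the uptake phase before the first scan;
  TIA from time zero inherits that approximation exactly as the clinical
  MTP procedure does.
* The exact Wilcoxon null is enumerated only up to 25 pairs (beyond that
  the tie-corrected normal approximation takes over).
* The copula correlation is a single scalar shared by all VOI types;
  kidney and lesion inter-cycle stability cannot currently be calibrated
  independently.
* The phantom path exercises segmentation geometry only; it contains no
  imaging physics.
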