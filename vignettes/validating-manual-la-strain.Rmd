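---
title: "Validating manual left atrial reservoir strain: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating manual left atrial reservoir strain: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lasrtools)
```

## The measurement model

The left atrium lengthens during ventricular systole as it fills against a
closed mitral valve; reservoir strain quantifies that lengthening. With the
reference configuration taken at the atrium's *maximal* (end-systolic)
length, the single-plane strain is `(Ls − Ld)/Ls` and the biplane value is
the mean over the apical 4-chamber and 2-chamber views, reported in percent:

```{r}
biplane_reservoir_strain(16.0, 14.7, 14.1, 12.9)
```

Two properties follow directly from the formula and are enforced by
property-style tests: the result is invariant to swapping the two views and
to rescaling all four lengths by a common factor (the formula is unit-free),
and it is strictly monotone in each length. Lengths are taken in
centimetres; because no unit conversion is ever applied, inputs outside
1–25 cm only trigger a plausibility warning.

Anomalous input — a diastolic length exceeding its systolic counterpart —
produces negative strain. We flag it (warning plus an `anomalous` field)
but do not reject or clamp: a validation pipeline must surface such rows,
not silently repair them.

When each patient is measured twice, `average_replicates()` combines the
replicates. We average the *computed biplane strains* by default rather than
the raw lengths: strain is the quantity of interest and averaging it keeps
each replicate's internal consistency; the alternative (`stage = "lengths"`)
is provided and the two agree to well under 0.01 strain-% for realistic
replicate differences.

## Agreement and reliability statistics

All comparisons are oriented **manual − automatic**, and all SDs use the
sample (n−1) denominator.

* **Bland–Altman.** Bias is the mean difference; the limits of agreement are
  `bias ± z·SD(diff)` with `z = 1.96` held fixed (not a t quantile). The
  fixed multiplier is the convention under which printed (bias, SD, LoA)
  triples in the agreement literature are mutually consistent, and its
  empirical coverage for normal differences converges to 95% (checked by
  simulation at n = 10⁵).
* **ICC(2,1).** Two-way random-effects, absolute-agreement, single
  measurement: `(MSR − MSE) / (MSR + (k−1)·MSE + (k/n)(MSC − MSE))` from the
  subject, rater and residual mean squares. The implementation reads the
  mean squares off `stats::aov`; the test suite checks it to 1e-9 against an
  independent brute-force sums-of-squares oracle on random matrices. The
  same operation serves inter- and intra-observer reproducibility on
  observer×repeat matrices.
* **CV of the differences.** `100 · SD(diff) / grand mean`, the grand mean
  being the mean of the two method means. Relative to that common level, the
  dispersion of the between-method differences is comparable across cohorts
  whose strain magnitudes differ several-fold.
* **SEM.** Two conventions exist side by side in the literature and they are
  *not* interchangeable: the reliability-based per-cohort form
  `SD(diff)·√(1 − ICC)` and the pooled form `SD(diff)/√2` (the within-subject
  SD when the two methods are treated as exchangeable repeats). Rather than
  picking one silently, `sem_measurement()` takes an explicit `mode`, every
  report labels which convention produced its value, and the pipeline
  defaults to the per-cohort form for group reports and the pooled form for
  the overall report. `MDC95 = 1.96·√2·SEM` follows whichever SEM is chosen.
* **Repeatability.** From duplicate measurements, `sw = √(Σd²/2n)` (the
  within-subject SD; generalised to m repeats via the within-subject mean
  square) and `RC = 1.96·√2·sw`. The RC confidence interval scales the point
  estimate by `√(df/χ²)`; we default to `df = n − 1` — treating the n
  within-subject differences as the sample whose spread is being bounded —
  with the textbook `df = n(m−1)` available behind `df_convention`. At
  n = 15 the two differ visibly (the default is wider), so the choice is
  explicit in `repeatability()`'s output.
* **Correlation inference.** Pearson r carries the usual t-transform
  p-value. Post hoc power uses the Fisher-z approximation with the standard
  small-sample mean correction `atanh(ρ) + ρ/(2(n−1))`; without that term
  the approximation misses the Monte-Carlo rejection rate of the r-test by
  ~0.014 at (ρ = 0.5, n = 30), with it the gap is ~0.003 (both checked in
  the suite at 2·10⁴ replicates). The correction vanishes at ρ = 0, so the
  null case returns exactly α.
* **Normality and categorical tests.** The KS normality check estimates mean
  and SD from the sample; the classical asymptotic p-value is conservative
  under estimation, so the Lilliefors-corrected variant is exposed behind a
  flag and the returned `method` says which was used. Categorical 2×2
  comparisons use the Pearson chi-square when all expected counts are ≥ 5,
  otherwise Fisher's exact test, again reporting which.
* **Multiple testing.** No adjustment anywhere: the workflow mirrors a
  single-study validation analysis in which each statistic answers its own
  question.
* **p-value floor.** p-values below 1e-300 are reported at that bound,
  matching the "< 10⁻ᵏ" presentation style of clinical tables and avoiding
  denormalised underflow.

## The synthetic cohort generator

No patient-level data ship with the package, so the study conditions are
emulated by a calibrated simulator. A cohort is described by the printed
summary triple (means, SDs, SD of differences); under bivariate normality
those five numbers fix the joint law, because
`cov = (sd_m² + sd_a² − sd_d²)/2`. Calibrating on the (mean, SD, sd_diff)
triple and letting r, ICC and the LoA *emerge* avoids over-constraining:
those statistics interlock and cannot be matched independently.

```{r}
implied_correlation(af_cohort_spec())
implied_correlation(sinus_cohort_spec())
```

The default conditions are two 30-patient cohorts: atrial fibrillation
(manual 6.53 ± 2.2 %, automatic 6.4 ± 2.3 %, sd_diff 0.71 %) and sinus
rhythm (29.5 ± 4.35 vs 30.3 ± 4.68, sd_diff 1.64). Bivariate normality is
the structure the downstream analysis itself assumes (normal-theory tests
throughout, KS normality screening), which is why it is also the simulation
model. About 0.2% of AF draws fall below zero; they are kept, since
truncation would distort the calibrated moments, and the generator counts
them in a message.

Duplicate-measurement sets for repeatability use a two-level model
(subject truth ~ Normal(grand mean, sd_between²); repeats add
Normal(0, sw²) noise) on a 15-patient subset per cohort and method. The
within-subject SDs are back-solved from target repeatability coefficients
as `sw = RC/(1.96·√2)` — derived calibration, not printed data. Covariates
(LAVi, EF, age from cohort-specific normal marginals; sex without
replacement so a 30-patient group has exactly 19 males) support the
subgroup stratifiers: LAVi > 34 mL/m², EF ≥ 50%, age ≥ 65, sex.

What the generator does *not* emulate: non-normal contamination, outliers,
proportional (magnitude-dependent) bias, repeated-measure drift, or any
imaging physics. Tests passing on simulated cohorts therefore demonstrate
that the statistical machinery is correct and well-calibrated under the
assumed model — not that the manual measurement would agree with automated
software on new patients.

## Auxiliary indices

The biplane area–length LA volume uses `8/(3π)·A1·A2/L` with `L` the
shorter of the two per-view lengths (`shorter_length()` takes the minimum
when both are present). The LV mass cube formula defaults to the
coefficient 1.4 with the Devereux constant 1.04 available via
`coefficient =`; reported LV mass values in the literature mix the two
conventions, so both are exposed rather than one silently chosen. The
Mosteller BSA helper is convenience plumbing for tables that carry
height/weight only.

## Numerical and design choices

* Full precision everywhere internally; rounding (1 decimal for strain
  percentages, 2 for agreement statistics, 3 for r/ICC) exists only in
  display strings, and the JSON report carries both so presentation never
  feeds back into computation. Doubles are serialized with 17 significant
  digits so they round-trip exactly.
* Every generator is a pure function of (spec, seed) and restores the
  caller's RNG state; the pipeline's default seed is 20250819.
* Degenerate inputs fail loudly and specifically: zero variance for
  correlation and KS, incomplete rating matrices for the ICC (no
  imputation), infeasible cohort specs named by the violated covariance
  bound, strata below n = 3 skipped with a warning rather than an error.
* Test problem sizes were chosen to make sampling error negligible against
  each tolerance while keeping the suite quick: 10⁵ draws for LoA coverage
  and moment convergence, 10⁴ subjects for sw consistency, 2000 replicates
  for RC interval coverage, 2·10⁴ for power Monte-Carlo, 10⁶ pairs for the
  correlation-recovery checks.

## Limitations

The package treats the automated speckle-tracking value as an external
reference; it does not process images, select frames, or trace endocardium.
Agreement statistics assume approximately normal differences (checkable via
`ks_normality()`); proportional-bias modelling, Deming or Passing–Bablok
regression are out of scope. Published per-cohort ICCs and Bland–Altman
biases from any particular study cannot be reproduced exactly without the
underlying patient data — the simulator recovers the *implied* population
quantities, and sampling variability at n = 30 is what the repeatability
and agreement machinery is there to quantify.
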