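---
title: "Cortico-striato-thalamo-cerebellar connectivity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cortico-striato-thalamo-cerebellar connectivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`cstcnet` implements a complete resting-state functional-connectivity
analysis of the circuit linking the cerebral cortex to the striatum,
thalamus and cerebellum: subcortical parcellation by winner-take-all (WTA)
partial correlation, 20-node network construction in both static and
sliding-window (dynamic) regimes, edgewise group statistics with
false-discovery-rate control, and discrimination of two patient groups with
an F-score-ranked linear support vector machine. Because clinical BOLD data
of this kind are rarely shareable, the package ships a synthetic-cohort
generator with planted ground truth; every stage of the pipeline is
validated against that truth.

## The signal model behind the generator

A session is a 4D grid (default 24 x 24 x 16 voxels) sampled at TR = 2 s for
250 volumes. Five band-limited (0.01-0.08 Hz) Gaussian latents
$s_1, \dots, s_5$ represent the activity of five cortical systems:
prefrontal, motor/premotor, somatosensory, parietal/occipital and temporal
cortex. Voxel series are built as

* cortical voxel of system $c$: $x_v(t) = s_c(t) + \varepsilon_v(t)$;
* subcortical voxel with planted affiliation $L(v)$:
  $x_v(t) = \alpha\, s_{L(v)}(t) + \beta \sum_{c \neq L(v)} s_c(t)
  + \varepsilon_v(t)$ with $\alpha = 1$, $\beta = 0.2$ (the
  winner-take-all structure is identifiable whenever $\alpha > \beta \ge 0$);
* every voxel additionally receives a shared global component (SD 0.3), a
  per-ROI regional fluctuation (SD 0.3), a linear drift, a small leak of the
  six pseudo-motion regressors, and i.i.d. noise (SD 0.5).

The regional fluctuation deserves a note: each of the 20 ROIs carries its
own band-limited component shared by its voxels. Without it the 20 ROI mean
series would live almost exactly in the 5-dimensional latent space and the
full 20-ROI partial-correlation estimator (which inverts the 20 x 20
covariance) would be ill-conditioned by construction. Spontaneous regional
activity not captured by a handful of distributed systems is also the
empirically realistic situation.

Planted effects are defined on named ROI pairs and applied to all voxels of
both ROIs through a shared band-limited source $e(t)$:

* a **static effect** of weight $\delta$ adds $\sqrt{|\delta|}\, e(t)$ to
  one ROI and $\mathrm{sign}(\delta)\sqrt{|\delta|}\, e(t)$ to the other,
  shifting their covariance by $\delta$;
* a **dynamic effect** of amplitude $a$ gates the shared source with a
  binary two-state series $g(t)$ (geometric dwell times), so the coupling
  alternates between "on" and "off" and the windowed correlation becomes
  genuinely time-varying;
* a **duration slope** plants a static effect of weight
  $\mathrm{slope} \times \mathrm{duration}$ per subject.

The mean dwell time of $g(t)$ defaults to 100 TRs. An earlier draft used
40 TRs, but with a 50-TR analysis window almost every window then straddles
a state switch, the windowed correlations are averaged across states, and
the planted variability effect becomes undetectable at realistic group
sizes. Dwells longer than the window guarantee that most windows observe a
pure coupling state.

Cohorts contain three groups — healthy controls (HC) and two patient
groups, generalized (GE) and focal (FE) epilepsy with tonic-clonic
seizures. Sex counts are matched exactly across groups (male fraction
75/114); ages are drawn from one common distribution; disease durations are
lognormal with moments matched to 7.98 (SD 8.32) years for GE and 9.42
(SD 6.56) years for FE.

A second, matrix-level generator (`simulate_edge_cohort()`) draws
per-subject 20 x 20 Fisher-z matrices directly from the same edge-effect
model with per-edge subject noise of SD 0.1, the order of the sampling
error of a Fisher-z estimate from 240 timepoints plus between-subject
variability. Replicated statistical calibration studies (null
false-discovery proportion over hundreds of cohorts, power curves,
interaction recovery) use this generator; voxel-level cohorts would add
nothing to those checks but hours of runtime.

## Preprocessing

The chain is fixed: discard the first 10 volumes; exclude any session whose
motion parameters exceed 1.5 mm translation or 1.5 degrees rotation (no
frame censoring); regress, per voxel, an intercept, a linear trend, the six
motion parameters, the mean white-matter signal, the mean CSF signal and
the global mean (the global regressor is on by default and can be
disabled); band-pass to 0.01-0.08 Hz.

The band-pass is an ideal rectangular filter in the frequency domain:
Fourier bins whose centre frequency lies inside the closed band are kept
unchanged, all others — including DC — are zeroed. This makes the filter an
orthogonal projection: in-band tones are preserved exactly, out-of-band
attenuation is total, and applying the filter twice is a no-op. Linear
drift removal lives in the nuisance design rather than inside the filter;
folding a detrend into the filter would break the projection property
(detrending a band-limited signal re-introduces small out-of-band
components).

The global mean is computed over the whole volume, not merely over the
ROI-labelled voxels. This is not cosmetic: if the global regressor were an
exact weighted sum of the 20 ROI means, regression would impose one exact
linear constraint on the ROI series and leave their covariance singular.

## Winner-take-all parcellation

For every voxel of the striatum, thalamus and cerebellum, the partial
correlation with each cortical-system mean signal is computed conditioning
on the other four signals (implemented as correlation of residuals after
projecting both series onto the orthogonal complement of the covariates,
and verified against that oracle at 1e-10 in the tests). The voxel is
labelled by the system with the highest **signed** coefficient; ties break
deterministically toward the lowest label index. Zero-variance voxels are
left unassigned with NA coefficients and are excluded from Dice
denominators and from ROI definitions.

The dynamic variant computes the same five coefficients inside each sliding
window (50 TRs, step 5), averages coefficients across windows and applies
WTA to the window means. Per-window coefficients use the same
partial-correlation operator as the static case: a 50-sample window
supports 4 covariates comfortably, and using one estimator in both regimes
keeps the static/dynamic comparison an apples-to-apples one.

Group maps average the per-voxel coefficient vectors across subjects and
re-apply WTA to the mean — a deterministic rule that uses the full
coefficient information. A voxel-wise majority vote is the obvious
alternative; it discards coefficient magnitudes and can produce ambiguous
ties at small n, which is why averaging was chosen.

Spatial agreement between maps is quantified by the Dice coefficient per
(structure, label) cell, optionally standardized by dividing by the
healthy-control value of the same cell. A label absent from both maps is
reported as absent, not as zero overlap.

## Networks

The 20 ROIs are the five cortical systems plus the five WTA subregions of
each subcortical structure, with subregions taken from the **static
healthy-control group map** and reused unchanged for every group — group
differences are then attributable to connectivity, not to shifting ROI
boundaries.

* **Static network**: partial correlation of each ROI pair conditioning on
  the remaining 18 series, from the inverse covariance
  ($r_{ij} = -p_{ij}/\sqrt{p_{ii}p_{jj}}$); coefficients are clipped at
  $|r| \le 1 - 10^{-6}$ and Fisher-transformed ($z = \mathrm{atanh}\, r$);
  the diagonal is fixed at 0. A ridge-style `shrinkage` argument is
  available for ill-conditioned input; the estimator refuses singular
  covariances with a pointer to that flag rather than silently
  regularizing.
* **Dynamic network**: per-window (50 TRs, step 5; count
  $\lfloor (T-w)/s \rfloor + 1$) plain Pearson correlation, clipped and
  Fisher-transformed. Windows of 50 samples cannot support 18-covariate
  partialing stably, so the per-window estimator deliberately differs from
  the static one.
* **dFC variability**: the entrywise sample standard deviation (denominator
  $n-1$) of z across windows — the "flexibility" of each connection.

Feature vectors for classification flatten the full 20 x 20 matrix
row-major: 400 entries per regime including the symmetric duplicates and
the zero diagonal, 800 for the combined set. The duplicates carry no new
information; the convention reproduces the canonical 400/400/800 feature
counts and the selection stage prunes redundancy anyway.

## Statistics

Edgewise analyses operate on the 190 unique off-diagonal edges: pooled
two-sample t-tests (Welch behind a flag), Pearson correlation with disease
duration, and an ordinary-least-squares interaction model
$z = b_0 + b_1\,\mathrm{group} + b_2\,\mathrm{dur} +
b_3\,(\mathrm{group}\times\mathrm{dur})$ with group coded GE = 0, FE = 1
(the coding is recorded in the result). Raw p-values are adjusted by
Benjamini-Hochberg over the 190-edge family; flattened 400-entry families
would double-count every edge and distort the FDR level. Edges with zero
variance are reported as NA and excluded from the family. Cohort balance
uses one-way ANOVA (age), Pearson chi-square without continuity correction
(sex x group) and pooled t-tests (duration, seizure frequency).

One honest caveat established during validation: when an effect is planted
between two ROIs at the voxel level, the **full partial-correlation**
network redistributes it — conditioning on a perturbed ROI changes other
edges' partial correlations too. Those edges are genuinely non-null, so
false-positive calibration cannot be read off a voxel-level planted cohort;
the FDR calibration studies therefore use the matrix-level generator where
nulls are exact, and the voxel-level cohorts check planted-edge detection.

## Classification

Stratified 10-fold cross-validation with strictly fold-internal selection:
inside each training fold, features are standardized by the training
mean/SD, ranked by the Fisher score
$F_i = \big[(\bar x_i^+ - \bar x_i)^2 + (\bar x_i^- - \bar x_i)^2\big] /
\big[s_i^{+2} + s_i^{-2}\big]$, and the retained count k is chosen from
{10, 25, 50, 100, 200, all} by inner 5-fold accuracy — the retained-feature
count is nowhere a free constant, and a leak test in the suite mutates
held-out rows and verifies that selection is unchanged. The classifier is a
linear SVM with C = 1 (exposed as an argument). Pooled accuracy,
sensitivity and specificity come from the concatenated held-out
predictions, AUC from the midrank statistic of the concatenated decision
values (constant decisions give 0.5). The positive class for sensitivity is
GE (+1), recorded in the result object.

Feature importance follows the weight-times-label reading: for feature $j$,
$\mathrm{imp}_j = w_j \sum_i y_i x_{ij}$ over the training subjects of each
fold, averaged across folds, with unselected features at 0. The formula is
implemented literally (signed, not $|w_j|$); the sign carries the direction
of separation.

## Reproducibility analyses

`split_half()` deals each group's subjects into two halves after sex
stratification and age sorting, alternating assignments and carrying the
alternation parity across strata so the halves differ by at most one
subject (114 subjects with 39 females split 57/57 with 20/19 females).
Half-to-half similarity is the Pearson correlation of the 190 unique
entries of the group-mean matrices. `window_sweep()` recomputes the dFC
variability pattern at windows of 30, 60 and 100 TRs and correlates each
against the 50-TR reference.

A limitation the generator makes explicit: on strictly stationary data the
dFC-variability pattern is nearly flat across edges (pure estimation
noise), so split-half correlation of that pattern hovers near zero — there
is simply no structure to reproduce. The split-half dFC check is therefore
run on a group carrying planted time-varying coupling, which is the
situation the clinical analysis faces.

## Problem sizes and numerical choices

The validation suite runs two scales, chosen once: a small geometry
(12 x 12 x 10 grid, 130 volumes) for unit tests — 130 volumes because after
the 10-volume discard the passband spans 17 Fourier bins, i.e. 34 real
degrees of freedom, comfortably above the 20 needed for full partial
correlation — and the reference geometry (24 x 24 x 16, 250 volumes, 10
controls for parcellation checks, 25 patients per group for classification)
for the acceptance checks. Calibration replicates use the matrix-level
generator (500 null cohorts at n = 20/group; 100 power cohorts at
n = 30/group with planted shift 0.3; 50 interaction cohorts at n = 57/group
with slopes of plus and minus 0.01 per year).

Numerical conventions collected in one place: correlations are clipped at
$1 - 10^{-6}$ before atanh; WTA ties break to the lowest label; the BH
adjustment delegates to `stats::p.adjust` and is tested against a hand
step-up; sample SDs use denominator $n - 1$; all randomness flows from
per-call seeds so that every cohort, fold assignment and split is exactly
reproducible.

## What passing tests do and do not show

The synthetic cohorts emulate band-limited signal content, planted
affiliation structure, group effects, duration dependence and nuisance
components — not hemodynamic response shapes, scanner noise spectra,
spatial autocorrelation from smoothing, or motion-induced artifacts beyond
the regressor tables. Recovery of planted structure at the default
signal-to-noise settings demonstrates that the estimators are implemented
correctly and are well-calibrated under the model's assumptions; it does
not certify effect sizes or accuracies on clinical data, where none of the
above idealizations hold.
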