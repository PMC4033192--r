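---
title: "Methods: the brain-age model, the marker statistics, and the synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the brain-age model, the marker statistics, and the synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(brainage)
```

This vignette is the package's own account of its science: the model and
its assumptions, the parameters that matter, what the synthetic generator
does and does not emulate, the numerical choices, and the limitations a
user should know before trusting a green test.

## 1. The brain-age model

### Preprocessing

Inputs are gray-matter (GM) density maps — unitless proportions in
[0, 1] on an isotropic grid — assumed already tissue-segmented and
affinely registered to a common space by an external tool; segmentation
and nonlinear normalization are deliberately out of scope. Three
operations follow, in this order:

* **Smoothing** (`smooth_volume`, default FWHM 8 mm). Separable Gaussian
  with `sigma = FWHM / (2 sqrt(2 ln 2))` in voxel units. The boundary is
  handled by nearest-value replication, chosen so that a constant field
  is an exact fixed point — a property the tests exploit — and so that no
  mass leaks out of the volume for interior-supported signals. The kernel
  is truncated at ±4 sigma and renormalized.
* **Resampling** (`resample_to_grid`, default 8 mm). Non-overlapping
  block means; trailing partial blocks average over the voxels that
  exist. Block-mean pooling (rather than interpolation) keeps the
  operation exactly linear and idempotent at factor 1.
* **Masking** (`build_mask`, default threshold 0.1). Voxels whose mean GM
  density across the *training* volumes exceeds 0.1 enter the feature
  matrix, a standard VBM-style analysis mask. The threshold is a
  convention; the underlying studies do not state one. The mask is fixed
  at training time and reused for every test subject.

The default synthetic grid is 24 × 28 × 24 at 4 mm, resampled to
12 × 14 × 12 at 8 mm — roughly 2 × 10³ features, honoring the 8-mm
working resolution of the emulated pipeline at desk scale.

### PCA

`fit_pca` is a centered SVD. All components with variance above
`1e-12 × leading variance` are retained by default. The component count
is genuinely an open choice in this family of pipelines; full retention
is the one choice that provably changes nothing downstream: an
orthonormal rotation preserves the training Gram matrix, so linear-kernel
regression on PCA scores equals regression on the raw centered features
(a property test asserts equality to 1e-6). PCA is kept in the pipeline
because it is part of the standard architecture and reduces the kernel
dimension from ~2000 voxels to at most n − 1 scores. Features are not
z-scored first: GM densities share one scale.

### Relevance vector regression

`fit_rvr` implements sparse Bayesian regression with the degree-1
polynomial kernel, realized as the homogeneous dot product plus an
explicit bias column, which is the same model as the inhomogeneous linear
kernel up to reparameterization. With design matrix `Phi = [1 | K]`,
`K_ij = x_i · x_j`, per-weight precisions `alpha` and noise precision
`beta`, each sweep computes

```
Sigma = (diag(alpha) + beta Phi'Phi)^-1
mu    = beta Sigma Phi' t
gamma_i = 1 - alpha_i Sigma_ii
alpha_i <- gamma_i / mu_i^2
beta    <- (N - sum(gamma)) / ||t - Phi mu||^2
```

pruning bases with `alpha > 1e12` and stopping when
`max |delta log alpha| < 1e-6` or after 1000 sweeps (then: warning and
best iterate — on large cohorts the slow tail of the alpha trajectory
routinely outlives the cap while predictions are long since stable).
Initialization is `alpha = 1/N²`, `beta = 10 / var(t)`, standard sparse
Bayes practice; no tuning is performed, in line with the framework this
reimplements, where parameter optimization was reported unnecessary. The
posterior solve for frozen hyperparameters equals a ridge solve, and a
dedicated test checks that identity against `solve()` to 1e-8.

**BrainAGE score** = estimated − chronological age. No post-hoc age-bias
correction is applied (none is described in the emulated framework);
held-out healthy cohorts are verified to have mean score within ±1 year
of zero instead.

## 2. Health-marker statistics

All branches hinge on `normality_test`, Shapiro-Wilk at alpha = 0.05
(constant vectors are degenerate and treated as non-normal with a
warning).

* **ANCOVA** (`ancova_gender`): `score ~ gender * marker`, fitting
  separate lines per gender. Main effects are Type-II (each adjusted for
  the other, excluding the interaction); the interaction is the increment
  over the main-effects model; all F denominators use the full-model MSE.
  The source material shows a three-F table but does not fix the
  sums-of-squares convention; Type-II is the order-independent choice
  matching `car::Anova`. When the full model is saturated (zero residual)
  a numerically zero effect SS reports F = 0 rather than 0/0.
* **PLS** (`pls_regression`): NIPALS PLS1 on z-scored predictors and
  centered response, complete cases only. The component count is chosen
  by leave-one-out PRESS — deterministic and defensible where the source
  is silent. Reported per marker: the regression weight on standardized
  predictors, the VIP score (mean square 1 by construction), and the
  share of explained variance attributed by normalized squared loading
  weights. The "most significant markers" are ranked by VIP — the
  standard ranking of the JMP-style PLS output the emulated analysis
  used; weights and explained-variance shares are reported alongside
  because the source describes both and the ranking between them is
  ambiguous.
* **Adjusted correlations** (`adjusted_correlation`): residualize both
  variables on age and one-hot site dummies (singleton sites pooled to
  avoid rank deficiency — with ~45 sites and ~110 subjects, many sites
  have one member and the exact encoding is undocumented), then Pearson
  or Spearman by normality of the residuals, p from the t approximation
  on residual df.
* **Quartile contrasts** (`quartile_contrast`): type-7 quantiles (pinned
  so group membership is reproducible); groups are `value <= Q1` vs
  `value >= Q3`; Student's t (equal variances) when both groups' scores
  pass the normality branch, Mann-Whitney otherwise; the effect is the
  absolute difference of group means in years; Holm correction with
  m = 4 across the top-marker family (`holm_adjust`, implemented from
  the step-down definition and cross-checked against `p.adjust`).
* **Combined groups** (`combined_group_split`): per-marker medians over
  the gender sample; "healthy" = at-or-below the median on every
  non-flipped marker and at-or-above on flipped ones (vitamin B12, where
  high is healthy); "risky" mirrored. Both definitions are literally
  inclusive, so subjects sitting exactly on all medians belong to both
  groups and are flagged — the source's wording implies this possibility
  without resolving it.
* **Missing data**: complete-case per analysis (PLS requires all 17
  markers; per-marker analyses require that marker), mirroring the
  published per-marker ns.

## 3. The synthetic world

The generator exists because the real training and test images are
access-controlled. It is a *stated world*, not a tuning dial: its
defaults are the published design quantities, and the few free parameters
were fixed once, as below, before the acceptance measurements.

* **Cohorts**: 561 training subjects aged 20–86 (mean 48.6, SD 16.5);
  118 male test subjects (75.8 ± 5.3, range 60–88) and 110 female
  (76.1 ± 4.8, range 62–90). Ages are truncated-normal; the parent
  mean/SD are solved (closed-form truncated moments) so the *truncated*
  distribution has the published moments — naive truncation of
  N(48.6, 16.5) would undershoot the SD by ~2 years.
* **Atrophy template** (`atrophy_field`): baseline density `b(v)` in
  [0.15, 0.9] and annual loss `s(v) = r(v)(b(v) − 0.05)/100`, both smooth
  Gaussian-blob mixtures under a fixed template seed (42) shared by
  training and test rendering. Tying the slope to the baseline keeps the
  noiseless signal strictly positive for brain ages beyond 110, so
  clipping never distorts the age signal. The magnitudes carry no
  anatomical claim; they only provide a spatially structured, linear age
  readout.
* **Voxel noise**: iid Gaussian, SD 0.05 at the native 4-mm grid, the
  one free noise parameter. After smoothing and pooling the model's
  held-out age error is ~0.5 years (r ≈ 0.999).
* **Markers**: drawn independently per marker from the published per-
  gender mean/SD; right-skewed markers (ALT, AST, bilirubin, creatinine,
  GGT, glucose, TSH, tHcy, triglycerides, B12) as moment-matched
  lognormal, the rest as positives-truncated normal. This reproduces the
  published normal/non-normal branch assignments qualitatively.
  Missingness is subject-concentrated: a small pool of incomplete
  subjects sized so the complete-case count matches the published PLS ns
  (107 male, 104 female) while per-marker observed ns match the baseline
  table.
* **Coupling** (`calibrate_effects`): subject brain age =
  chronological + Σ γ_m z_m + ε. Targets are the published quartile
  contrasts (male: BMI 7.5, DBP 6.6, GGT 7.5, uric acid 5.6 years;
  female: GGT 6.1, AST 3.1, ALT 5.1, B12 −4.8, the negative sign
  encoding protection). For any marker monotone in its latent z the
  expected contrast per unit γ is `2 φ(z₀.₇₅)/0.25 ≈ 2.5426`; the normal
  family uses the closed form, lognormal families a 10⁶-draw Monte Carlo
  under a fixed calibration seed. The residual SD is then root-solved so
  the *in-sample* PLS R² at the published complete-case n matches the
  published 0.39 (male) / 0.32 (female) — in-sample because that is what
  the emulated analysis reported; calibrating the population fraction
  instead would overshoot by the finite-sample optimism (~p/n ≈ 0.15).
* **Determinism**: everything derives from one seed through a Lehmer-step
  `seed_stream`; identical configs give bit-identical cohorts.

### What a green test does not establish

* Healthy training/held-out subjects have brain age exactly equal to
  chronological age — no inter-individual biological variability — so the
  held-out age-estimation r (~0.999) exceeds the r = 0.92 reported on
  real adults. The corresponding acceptance criterion is a lower bound,
  honestly cleared for the wrong reason: iid voxel noise cannot produce a
  realistic 6-year estimation error within the [0, 1] density range, and
  the generator's contract fixes the noise model. Treat the accuracy
  figure as a pipeline noise floor, not a claim about real MRI.
* Markers are generated mutually independent; real liver enzymes, lipids
  and blood pressure correlate substantially. Calibration of per-marker
  contrasts is exact only because of this independence.
* Markers are independent of chronological age in the generator; real
  elderly cohorts confound the two. The adjusted-correlation stage is
  therefore exercised structurally, not against a planted confound.
* No scanner/site effects enter the images — the site label is pure
  noise — so the site ANOVA is expected null, as in the emulated data.
* Cognitive scores are drawn independently of brain age (the emulated
  analysis found no quartile-group differences), so the cognitive tables
  only verify plumbing and type-I behavior.

## 4. Numerical choices and degenerate inputs

* Smoothing kernel truncated at ±4 sigma; FWHM 0 is the identity.
* `fit_rvr` floors `mu²` at 1e-300 and `gamma` at 1e-12 to avoid 0/0 in
  the alpha update; a Cholesky failure retries once with a 1e-10 jitter.
  Constant targets collapse to a bias-only model rather than erroring.
* `pls_regression` flags a constant response as degenerate (R² 0, VIP
  NA); constant predictors are an error (they carry no direction).
* Quartile splits error when Q1 = Q3 (massive ties) rather than
  fabricating groups; two zero-variance groups with equal means compare
  at p = 1 by convention with a warning.
* Holm: the step-down running maximum is capped at 1; inputs outside
  [0, 1] are errors, not clamps.
* All report floats are written at 6 significant digits.

## 5. Known limitations

* The NIfTI-1 reader/writer is minimal by design (single-file, isotropic
  3D, five datatypes, header diagonal only); it is not a general
  neuroimaging I/O layer.
* The RVR iteration cap (1000 sweeps) is routinely hit at n = 561; the
  returned iterate is stable to well below the estimation noise, but the
  convergence warning is surfaced rather than suppressed.
* Exact numeric reproduction of the original framework's estimates is
  not claimed: whether the original applied RVR to PCA scores directly
  or with additional normalization is undocumented; the isometry
  argument above makes the choice immaterial for the linear kernel, but
  only within this package's conventions.
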