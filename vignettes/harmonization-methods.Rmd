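---
title: "Methods: CT radiomic feature harmonization with ComBat and longComBat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CT radiomic feature harmonization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`radharmon` removes acquisition-protocol (batch) effects from CT radiomic
feature tables. This vignette documents the models, the numerical choices,
the synthetic-data generator, and the limits of what the package's tests
demonstrate.

## The location/scale batch model

A feature table has one row per lesion image (lesion × timepoint) and one
column per feature. Batches are acquisition protocols: each observed
(convolution kernel, kVp) combination receives an integer label
(`assign_batches()`, lexicographic numbering by default; a user-supplied
mapping can impose any published numbering). The working model for feature
$g$, observation $j$ in batch $i$ is

$$Y_{ijg} = \alpha_g + \sigma_g\,(\gamma_{ig} + \delta_{ig}\,\varepsilon_{ijg}),
\qquad \varepsilon_{ijg} \sim (0, 1),$$

with a per-batch additive effect $\gamma_{ig}$ on the standardized scale and
a multiplicative residual-variance effect $\delta_{ig}^2$.
`combat_standardize()` estimates $\hat\alpha_g$ as the batch-size-weighted
mean of batch means and $\hat\sigma^2_g$ as the mean squared residual after
removing batch means; under this convention the size-weighted sum of the
per-batch location effects is zero by construction. No biological
covariates are modeled: the intended use case is a clinically homogeneous
cohort in which no biological signal needs to be explicitly protected. A
covariate-free model also means the harmonizer will remove *any* signal
confounded with protocol — users with heterogeneous cohorts should be aware
of this.

### Empirical-Bayes modes

Three estimators of $(\gamma^*_{ig}, \delta^{*2}_{ig})$ are exposed, because
"ComBat" in the radiomics literature refers to any of them:

* **no_eb** — the raw within-batch moments of the standardized data. Under
  this mode the adjusted per-batch means and variances equal the pooled
  estimates *exactly* (an algebraic identity the tests verify to 1e-9).
* **parametric_eb** — normal prior on $\gamma$, inverse-gamma prior on
  $\delta^2$, hyperparameters by method of moments across features within
  each batch, then the coupled conditional-posterior updates
  $$\gamma^* = \frac{n_i\tau^2\hat\gamma + \delta^{*2}\bar\gamma}
  {n_i\tau^2 + \delta^{*2}}, \qquad
  \delta^{*2} = \frac{\theta + \frac12\sum_j (Z_{ijg}-\gamma^*)^2}
  {n_i/2 + \lambda - 1}$$
  iterated to a fixed point. Convergence is declared when the maximum
  absolute change drops below `eb_tol` (default 1e-4; tests use 1e-12 and
  compare against an independently written damped solver at 1e-10).
  Non-convergence within `eb_max_iter` is an error, never a silent result.
* **nonparametric_eb** — the default, and the configuration used for the
  headline results: posterior estimates are likelihood-weighted leave-one-out
  averages of the other features' moment estimates, with weights
  $w_{g'} = \prod_j N(Z_{ijg}; \hat\gamma_{ig'}, \hat\delta^2_{ig'})$
  computed in the log domain (a max-subtraction softmax; if every weight
  underflows even there, the estimator falls back to the unweighted mean
  with a warning). The full deterministic sum over features is always used
  — no Monte-Carlo subsampling — so results are exactly reproducible.

The adjustment is
$Y^* = (\hat\sigma_g/\delta^*_{ig})(Z_{ijg}-\gamma^*_{ig}) + \hat\alpha_g$.
Zero-variance features cannot be standardized; they are flagged and passed
through unchanged so the table keeps its shape.

One practical note the tests surfaced: the nonparametric mode borrows
strength across features, and with very few features (fewer than ~10) the
leave-one-out average can be badly biased when batch effects differ across
features, leaving residual batch dependence. At the intended scale
(42 features) the weights concentrate appropriately and the residual
dependence rate drops to the null level.

### Variance-denominator conventions

At protocol-harmonization batch sizes (down to $n_i = 2$) the $n$ vs
$n-1$ convention visibly changes results, so both are explicit in
`combat_config()`: pooled variance over $N$ (default) or $N-K$;
within-batch variance with $n_i - 1$ (default) or $n_i$. The single-batch
identity ($Y^* = Y$) holds exactly only when the two conventions match
degrees of freedom (`sigma2_denominator = "n-k"` with
`delta2_denominator = "n-1"`); the defaults instead match the convention of
the reference cross-sectional implementation, against which the test suite
verifies numerical agreement.

## Longitudinal ComBat

When lesions are imaged at two timepoints, observations are not
independent. `longcombat_fit()` fits, per feature, the REML linear mixed
model
$$y = \alpha + \beta_{time}\,I(\text{follow-up}) + \gamma_{batch}
+ b_{subject} + \varepsilon, \qquad b_s \sim N(0, \sigma_b^2),$$
re-expresses the batch coefficients under the size-weighted sum-to-zero
constraint, standardizes residuals by the REML residual SD, shrinks batch
effects with the same parametric-EB fixed point (the longitudinal variant
has no nonparametric mode), and removes them while adding back the fitted
fixed part and subject intercepts:
$$y^* = \frac{\sigma}{\delta^*_i}\left(\frac{y - \text{fixed} - \hat b_s}
{\sigma} - \gamma^*_i\right) + \text{fixed} + \hat b_s.$$

Design choices:

* **Random intercepts only.** Two timepoints cannot identify random
  slopes; the intercept-only structure is the richest identifiable one.
* **Timepoint as a two-level fixed effect** (baseline / follow-up), which
  is the design of the motivating study type; general time courses are out
  of scope.
* **Eligibility before fitting** (`filter_longitudinal()`): subjects need
  at least two timepoints and batches at least one observation; ineligible
  subjects and emptied batches are removed iteratively and logged, never
  imputed.
* **Degenerate fits.** Rank-deficient batch designs (e.g. a batch
  perfectly confounded with timepoint) flag the feature, which is passed
  through unharmonized. A singleton batch carries no scale information;
  its $\hat\delta^2$ is set to 1 and the EB posterior is then dominated by
  the prior.
* Within a subject whose two images share a batch, harmonization maps the
  follow-up-minus-baseline contrast as
  $(d - \beta_{time})/\delta^*_i + \beta_{time}$ — trajectories are
  preserved exactly when no scale effect is estimated, and their ordering
  is never changed by a location-only correction.

## Screening and assessment

`screen_parameters()` ranks candidate acquisition parameters by the number
of features with Kruskal–Wallis $p < \alpha$ across their levels, then
excludes, in order: (1) a-priori exclusions — by default tube current,
because dose modulation renormalizes image quality and decouples mA from
texture in heterogeneous tissue; (2) parameters missing in more than 50% of
observations; (3) the weaker member of any pair with Cramér's V above 0.8
(the threshold is a package choice — "strongly associated" needs a number —
and is configurable); (4) parameters with zero significant features.

`significance_rate()` tests features independently at $\alpha = 0.05$ with
**no multiplicity correction**, matching the screening convention of the
harmonization literature this workflow reproduces; a Benjamini–Hochberg
flag is available for users who want corrected decisions. Kruskal–Wallis
uses the tie-corrected $H$ and the chi-square upper tail; an input with all
values tied returns $H = 0, p = 1$ by convention.

Two small-sample facts matter at these batch sizes and are deliberately
documented rather than hidden:

* Chi-square p-values are asymptotic; with 14 groups, several of size 2,
  the true rejection rate at nominal 0.05 is about 0.035–0.042 (measured by
  Monte Carlo against base R's implementation, with which the package
  agrees exactly). Type-I error is therefore *controlled* (conservative)
  at the study profile; the binomial-null calibration check in the test
  suite uses 4 balanced groups of 30, where the approximation is accurate.
  An exact permutation p-value mode (`p_method = "exact"`, full
  enumeration) exists for validation at very small n.
* Because the assessment reuses the data the harmonizer was fitted on,
  post-harmonization p-values are not strictly uniform; the no-EB mode
  equalizes batch moments exactly, making the post-harmonization test
  conservative by construction.

## The synthetic-data generator

The generator produces exactly the structure the harmonizer assumes, plus
the longitudinal structure the mixed model assumes:

* Default batch design: 14 batches with the lesion frequencies
  5, 17, 12, 25, 2, 19, 9, 9, 4, 7, 11, 2, 2, 2 (126 observations) and the
  corresponding (kernel, kVp) labels of the reference multi-center
  protocol profile; scanner labels derive deterministically from the
  kernel family, which gives the screening step a realistic
  strongly-associated parameter pair.
* Batch-level location shifts evenly spaced in $[-1.5, 1.5]$ (standardized
  units, "order 1") and scale factors log-spaced in $[0.5, 2]$. Per-feature
  effects are drawn around the batch-level values
  ($\gamma_{ig} \sim N(\gamma_i, 0.5^2)$,
  $\log\delta^2_{ig} \sim N(\log\delta^2_i, 0.25^2)$) — exactly the
  across-feature heterogeneity empirical Bayes is designed to shrink. The
  magnitudes are chosen for test power (effects large enough that failure
  to harmonize is unmistakable), since no real-data effect sizes are
  available to emulate.
* Longitudinal mode: one subject per lesion, two timepoints, a subject
  intercept $b_s \sim N(0, 1)$ in raw feature units shared across a
  subject's rows (giving the closed-form intraclass correlation
  $\sigma_b^2/(\sigma_b^2 + \sigma_g^2\delta^2)$ the tests check) and a
  follow-up shift of 0.5 feature SDs. Each image draws its own batch,
  mirroring re-scanning under a different protocol.
* Residuals are Gaussian by default — that is what gives closed-form
  checks — with a unit-variance Student-t option (`residual_df`) to
  exercise the nonparametric adjustment's motivation.
* Determinism: one master seed; every random stream (effects, residuals,
  metadata, batch shuffling) derives a child seed from it, so equal seeds
  give bit-identical tables.

What the generator does **not** emulate: kernel-specific noise texture,
scanner physics, correlated features (features are generated
independently), informative dropout, or more than two timepoints. Passing
tests on this generator demonstrate that the estimators recover and remove
the effects of their own model class at realistic sample sizes — not that
real CT batch effects are this well-behaved.

## Feature extraction

Preprocessing follows the fixed recipe: trilinear resampling of HU to
1 × 1 × 1 mm (nearest-neighbor for the mask, re-binarized), then absolute
discretization over $[-1000, 3000]$ HU into 400 bins of 10 HU. Bins are
half-open with the top edge closed and levels are 1-based; out-of-range HU
clamp to the boundary levels and are counted and reported. Resampling
precedes discretization so that interpolation acts on HU, never on integer
levels. ROIs below 64 voxels are rejected.

Matrix conventions (all verified cell-by-cell against brute-force
enumerators on small phantoms): GLCM pools symmetric co-occurrences over
the 13 unique 3D directions at Chebyshev distance 1 and normalizes to
sum 1; GLRLM pools maximal equal-level runs over the same 13 directions
(run percentage is normalized by 13 × voxel count so its upper bound is 1);
GLZLM zones are 26-connected components; NGLDM summarizes the
26-neighborhood restricted to in-ROI neighbors. Texture features use the
actual discretized level values, not compressed ranks. Surface area for
sphericity/compacity counts exposed voxel faces — deterministic and
oracle-checkable; a meshed surface would be smoother but is out of scope.
Degenerate inputs follow fixed conventions chosen so valid input never
yields NaN: a single-level ROI has GLCM correlation 1, zero histogram
skewness/kurtosis, and zero NGLDM coarseness/contrast/busyness.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on synthetic data at
the study scale the package targets: tables of 42 features × 126
observations (14 batches), mixed-model fits over 20 replicate seeds, null
calibrations over 60–200 replicates, and phantoms up to 8³ voxels for
exact oracle comparisons. These sizes make every check exact or tightly
calibrated while keeping the whole suite in a few minutes on one core.

## Known limitations

* Covariate preservation (protecting biological contrasts during
  harmonization) is not implemented; the model is deliberately
  covariate-free.
* The longitudinal variant offers only parametric EB, mirroring the state
  of the longitudinal methodology.
* DICOM ingestion, 2D extraction, filtered/wavelet feature classes and
  predictive modeling downstream of harmonization are out of scope.
* Batch numbering is deterministic but lexicographic; reproducing a
  published protocol numbering requires passing that mapping explicitly.
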