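---
title: "Regional homogeneity mapping and cluster-extent inference: methods"
author: "rehopipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional homogeneity mapping and cluster-extent inference: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rehopipe)
```

## The measure

Regional homogeneity (ReHo) quantifies how synchronously a voxel's BOLD
time course evolves with its immediate surroundings.  For a voxel and its
in-mask neighbors — $K$ series of $n$ time points — each series is
converted to mid-ranks over time and concordance is measured by Kendall's
coefficient of concordance,

$$W = \frac{12\,S}{K^2(n^3-n) - K\sum_j T_j}, \qquad
S = \sum_t \left(R_t - \bar R\right)^2,$$

where $R_t$ is the rank sum across series at time $t$ and
$T_j=\sum_g (t_g^3-t_g)$ is the usual tie correction over tie groups $g$
of series $j$.  $W=1$ means identical rank orderings; under independence
$E[W] = 1/K$.  `kcc()` implements exactly this statistic; `reho_map()`
evaluates it at every in-mask voxel over a 27-voxel neighborhood by
default (7 and 19 are available for comparability with the wider ReHo
literature).

Two numerical choices deserve note:

* **Ties.** Continuous BOLD essentially never ties, but quantized or
  synthetic data can.  Mid-ranks plus the $\sum_j T_j$ correction are the
  default (`tie_correction = TRUE`); the uncorrected form is available
  because some historical toolchains omitted it.
* **Mask edges.** A voxel keeps its reduced set of in-mask neighbors
  (smaller $K$) rather than being dropped; voxels left with $K<2$ are set
  to 0 and *flagged*.  Flagged voxels are excluded from the
  standardization mean and from group inference: their value is a policy
  artifact, not data.

Maps are then **standardized** by the within-mask mean (mask mean becomes
exactly 1) and **smoothed** with an isotropic Gaussian kernel
($\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$, default 6 mm), in that order.
Smoothing is mask-renormalized — the kernel is restricted to in-mask,
unflagged voxels — so no zeros bleed in from outside the brain and a
constant map is left unchanged.

## Preprocessing

The temporal chain mirrors the standard resting-state recipe:

1. `discard_initial_volumes()` — drop the first 10 volumes (signal
   equilibration; 180 acquired volumes leave 170).
2. `qc_motion()` — exclude a dataset if any translation exceeds 1.5 mm or
   any rotation exceeds 1 degree on any axis.  Rotation units must be
   declared by the caller (`read_motion_params(path, rotation_unit=)`):
   the SPM `rp_*.txt` dialect stores radians while thresholds are quoted
   in degrees, and a silent unit mismatch is the classic QC bug.  The
   screen is applied to the retained volumes; motion files with one row
   per acquired volume are truncated accordingly.
3. `detrend_linear()` — per voxel, subtract the least-squares line over
   time and restore the temporal mean.  Ranks are offset-invariant, so
   keeping the mean is cosmetic, but it makes the contract testable
   (output mean equals input mean to 1e-10).
4. `bandpass_ideal()` — frequency-rectangular filter keeping DFT
   components with $0.01 \le f \le 0.08$ Hz (inclusive edges, judged on
   the exact DFT frequency), the sharp-edged convention of the REST
   toolchain.  The DC component is retained so the mean survives.  A
   sharp filter leaks a little of a non-bin-aligned out-of-band sine
   (about 2–3% in RMS at 0.12 Hz with 170 volumes at TR 3 s); this is a
   property of the ideal-filter convention itself, not of the
   implementation.

Spatial preprocessing (slice timing, realignment, normalization to a
template) is deliberately out of scope: inputs are assumed to already sit
on a common 3 mm grid, which is also the grid the synthetic generator
produces.

## Group model

`fit_group_glm()` fits, per voxel, ordinary least squares of the
standardized smoothed ReHo value on
$[\,\mathrm{intercept}, \mathrm{group}, \mathrm{age}, \mathrm{sex},
\mathrm{education}\,]$, with continuous covariates mean-centered (the
group coefficient and its $t$ are unchanged; conditioning improves) and
sex coded as a single indicator.  The reported statistic is
$t = \hat\beta_{\mathrm{group}} / \mathrm{SE}$ with
$\mathrm{df} = N - p$; with 89 subjects and 5 columns, df = 84.  With no
covariates this is algebraically the pooled-variance two-sample $t$,
which the tests verify to 1e-8.  A covariate with zero variance (e.g. an
all-male subsample) carries no information and is dropped with a warning;
genuine collinearity is an error naming the offending columns.

Post-hoc, `partial_correlation()` correlates cluster-mean standardized
ReHo with clinical smoking variables in the smoker group only (the
variables exist only there), controlling for age, sex and education:
Pearson correlation of the two OLS residual vectors, with
$t = r\sqrt{(N-2-k)/(1-r^2)}$ on $N-2-k$ df.  No multiplicity correction
is applied across clinical variables, matching the two-tailed p < 0.05
convention of the analysis this package operationalizes.  A variable
exactly explained by the covariates has zero residual and is assigned
$r = 0$; a constant input is an error.

## Cluster-extent correction

`alphasim_null()` implements the Monte-Carlo cluster-size simulation of
the AlphaSim tradition: fill the mask's bounding grid with i.i.d.
standard normal noise, smooth to a target FWHM, restrict to the mask,
re-standardize, threshold two-tailed at the voxelwise $p$, and record the
maximum cluster size over both signs.  `extent_threshold()` returns the
smallest $k$ with
$\Pr(\max \mathrm{size} \ge k) \le \alpha_{\mathrm{corrected}}$; clusters
of size $\ge k$ are declared significant.  Positive and negative clusters
are formed separately, and the null records the maximum over both signs,
so the corrected alpha is two-tailed.  The same connectivity parameter
(default 6, face contact; 18 and 26 available) feeds both the null and
`report_clusters()`, so the two sides of the calibration can never
diverge.  Cluster peaks are located at the maximum $|t|$, ties broken to
the smallest linear voxel index, and converted to world mm through the
NIfTI affine (0-based voxel indexing).

### Which FWHM to simulate

The classical parameter choice feeds the *nominal* map-smoothing FWHM
(6 mm) to the simulation.  That choice is anti-conservative here: the
ReHo operator itself (a 27-voxel window on noise that is already 6 mm
smooth) plus the 6 mm map smoothing leave second-level residuals
smoother than the nominal value — the integration test asserts the
estimated FWHM exceeds 6 mm — and a too-rough null underestimates
cluster sizes, inflating the family-wise error above the corrected
alpha.  `run_pipeline()` therefore defaults to `mc_fwhm_mm = "estimate"`:
`estimate_fwhm()` applies the standard first-difference smoothness
estimator,

$$\mathrm{FWHM}_{\mathrm{axis}} = d\,\sqrt{\frac{-2\ln 2}
{\ln\!\left(1 - \sigma^2_\Delta / 2\sigma^2\right)}},$$

to the second-level residual maps (geometric mean over axes, mean over
subjects), the same idea behind AFNI's `3dFWHMx` + `3dClustSim`
workflow.  Setting `mc_fwhm_mm = 6` reproduces the nominal convention
when comparability with legacy results matters.  The extent threshold
derived from one null can be reused across analyses of the same mask and
parameters by passing `null_dist` to `run_pipeline()` — exactly how a
single published cluster-size criterion is applied to a study's map.

## The synthetic cohort generator

Because no scan data ship with the package, `generate_cohort()` produces
cohorts with the statistical structure the analysis assumes:

* **Background**: voxelwise Gaussian AR(1) noise (lag-1 coefficient 0.3,
  a plausible BOLD autocorrelation at TR = 3 s), spatially smoothed to
  `noise_fwhm_mm` (default 6 mm) and rescaled to unit SD.
* **Effects**: spherical ROIs whose voxels mix a *shared* band-limited
  (0.01–0.08 Hz) unit-variance signal into their series:
  $x \leftarrow \sqrt{1-w^2}\,x + w\,s$ with a group-specific coupling
  weight $w \in [0,1)$.  Restricting the shared signal to the passband
  guarantees the planted synchrony survives filtering.  In-ROI ReHo is
  monotone in $w$, and $w=0$ is statistically indistinguishable from
  background.
* **Covariates**: drawn from the demographic structure of a two-group
  smoking study (45 smokers / 44 non-smokers; ages ≈ 27.9 ± 5.6 vs
  26.3 ± 5.8 years; education 13.1 ± 3.0 vs 15.0 ± 2.6 years; about 18%
  vs 23% female; cigarettes/day 20.3 ± 7.6, years smoking 10.2 ± 5.8,
  craving score 6.41 ± 1.7, clinical fields present for the smoker group
  only).  Continuous draws are clamped to the plausible published
  ranges.
* **Clinical link** (optional): a subject's coupling weight in one ROI is
  shifted by $0.2 \cdot \mathrm{strength}$ per SD of a clinical variable
  (clamped to $[0, 0.99]$), inducing a positive clinical–ReHo
  correlation of tunable size.  The strength is a free parameter: the
  study this design mirrors reported *no* significant clinical
  correlations, so there is no empirical effect size to match.
* **Motion**: a 6-parameter random walk (per-step SD 0.02 mm / 5e-4 rad)
  written in the SPM `rp_*.txt` dialect, small enough that QC passes
  almost always while exercising the reader and the gate.

Identical `(config, seed)` reproduce every voxel, covariate and file
bit-for-bit; per-subject seeds are derived from the master seed.

What the generator does **not** emulate: scanner drift beyond a linear
trend, spikes, physiological noise, registration error, anatomical
structure in the mask, and spatial non-stationarity of smoothness.
Passing tests therefore demonstrate the *statistical machinery* —
calibration of the null, recovery of planted effects, covariate
adjustment — not robustness to real-scanner artifacts.

## Problem sizes used in the tests

Full-scale defaults (89 subjects, 180 volumes, an MNI-like 61×73×61
grid) are faithful but far larger than needed to exercise the
statistics, so the test suite and the acceptance study run scaled
conditions chosen once: two groups of 10, a 16³ grid at 3 mm, 60 volumes
at TR 3 s (50 analyzed), 6 mm noise smoothness; the family-wise-error
study uses 100 null cohorts against a 1000-iteration Monte-Carlo null,
and the planted-effect study uses a radius-3 sphere with coupling 0.8 vs
0.2 over 10 seeds.  Null-distribution calibration of the voxelwise $t$
statistics is checked on spatially independent background with a
spacing-3 voxel subsample, so the Kolmogorov–Smirnov test sees
effectively independent draws.

## Known limitations

* The ideal band-pass assumes stationarity and leaks slightly around
  sharp out-of-band components; tapered filters are deliberately not
  offered to keep the REST-convention semantics.
* The Monte-Carlo null assumes Gaussian, stationary, isotropic fields.
  ReHo maps are bounded and mildly skewed; at the tested scale the
  residual-smoothness null is slightly conservative (empirical FWE below
  the corrected alpha), which we consider the right side to err on.
* Anatomical labeling of clusters is a free-text passthrough; no atlas
  ships with the package.
* `estimate_fwhm()` assumes smoothness is spatially stationary within
  the mask.
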