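---
title: "Methods: simulating and discriminating transient versus persistent part-solid nodules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and discriminating transient versus persistent part-solid nodules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Part-solid nodules (PSNs) on thin-section chest CT combine a hazy
ground-glass component with a denser solid core. A large fraction of
incidentally detected PSNs are transient inflammatory lesions that shrink
or disappear within about three months, while persistent PSNs carry a
high probability of adenocarcinoma. Telling the two apart at the first
scan matters: it decides between short-interval follow-up and aggressive
work-up. `psntexture` implements a quantitative route to that
discrimination: first-order histogram texture features of the nodule's
Hounsfield-unit (HU) pixel distribution, combined with clinical and CT
covariates in logistic models whose C-statistics are compared with the
DeLong test for correlated ROC curves.

Because the patient images behind the published group statistics were
never deposited, the package also contains a first-class synthetic-data
module: a generator of CT-like nodule images whose group-level feature
statistics are *calibrated* to the published tables, so that the entire
image-to-inference pipeline is testable end to end without any download.

## The synthetic nodule generator

A nodule is simulated as two concentric disks on an aerated-lung
background:

* background pixels `N(mu_bg, sigma_bg)`, default `-870 +/- 30` HU — a
  plain aerated-lung stand-in; only its contrast against the nodule
  matters and calibration absorbs the choice;
* a ground-glass disk of diameter `d` with pixels `N(mu_gg, sigma_gg)`;
* a concentric solid core of diameter `solid_frac * d` with pixels
  `N(mu_solid, sigma_solid)`.

The noiseless three-level class map is blurred with a Gaussian kernel of
full width at half maximum `blur_fwhm_mm` *before* noise is added; the
blur is the generator's knob for margin definition (a large blur makes
the ill-defined margin typical of transient lesions, letting background
bleed into the rim of the nodule and pulling the low percentiles of the
whole-nodule histogram toward lung attenuation). Pixels are rounded to
integer HU and clamped to the 12-bit CT range `[-1024, 3071]`. The
annotation contours trace the two noiseless disk boundaries, mimicking
manual whole-nodule and solid-portion segmentation.

Geometry follows the published CT-feature table: lesion diameters are
truncated normal on `[5, 30]` mm (the study's inclusion range) with
group means/SDs `10.9 +/- 3.4` mm (transient) and `14.7 +/- 6.3` mm
(persistent); the solid-portion diameter fraction is truncated normal on
`(0.05, 0.95)` with means `0.469` and `0.479`. Pixel spacing defaults to
0.7 mm, a typical thin-section chest-CT in-plane resolution (512 matrix
over a ~35 cm field of view). The canvas leaves a background margin of
at least one diameter on each side of the nodule.

The generator produces single 2D slices although clinical acquisitions
are 3D stacks: every feature the package computes is a pixel-population
statistic (or a per-boundary-point profile average), invariant to
whether pixels are pooled across slices, and 2D keeps the simulation at
desk scale. One annotated slice per nodule is therefore the modeled
unit.

### Calibration

`calibrate_generator()` tunes the five free HU parameters (`mu_gg`,
`sigma_gg`, `mu_solid`, `sigma_solid`, `blur_fwhm_mm`) so that the group
means over simulated nodules of four extracted whole-nodule statistics —
mean attenuation, per-nodule pixel SD, skewness and the 5th-percentile
CT number — match the published group values stored in
`psn_table_targets()`. The search is Nelder-Mead over a box of
physically plausible values, with each objective evaluation simulating
200 nodules on a fixed seed stream (common random numbers make the
objective deterministic and the simplex well behaved). Gaps are z-scaled
by the acceptance tolerances — 5% of the target magnitude for HU
statistics, 0.15 absolute for skewness — and calibration fails loudly,
reporting residuals, if any target is missed. The shipped
`psn_preset()` image parameters are the product of exactly this
procedure and are verified on independent seeds by the test suite.

The calibration targets the published *means* only. The published
transient skewness SD (0.060) is implausibly small next to the
persistent group's 0.567 and is likely a typographical artifact; no
dispersion target is used for skewness.

### Clinical covariates and labels

Clinical records are drawn per patient from the published group
distributions: age (normal truncated to `[18, 90]` years), sex, smoking
and lesion multiplicity (Bernoulli), white-cell count, eosinophil count
and C-reactive protein (normals truncated at zero — the tables give only
mean +/- SD for these positive quantities, so the truncated normal is
the minimal distributional commitment). Eosinophilia is derived as a
count above 500 cells/uL; the source table's "/mL" unit is treated as a
slip for /uL, since hundreds of cells per *milliliter* would be
physiologically meaningless and the table header itself reads u/L.

The transiency label is operationalized exactly as the clinical rule:
transient if the follow-up size is at most 80% of baseline within 92
days (3 months; the rule's day count is a package choice, the source
gives none), persistent if the size stayed within a 5% stability band or
grew over at least 92 days (`epsilon_stable = 0.05` is likewise a
package choice — no numeric stability criterion exists in the source).
Anything else is `"indeterminate"` and excluded downstream. The cohort
generator draws follow-up plans that satisfy the label of the nodule's
group by construction, and the test suite asserts that consistency.

Patients flagged for multiplicity receive 2–3 nodules sharing their
clinical covariates. The multiplicity probabilities are taken from the
published multiplicity split per group (16/31 and 9/46); patient counts
are then emergent rather than forced to the published 31/46, because the
published nodule and patient counts are not jointly consistent with any
single per-patient multiplicity rule.

Realized correlations among texture features (and between texture and
geometry) are emergent from the image model; the source reports no
inter-feature correlations, so nothing is matched to them. Passing tests
therefore demonstrate calibration of group-level marginals, not of the
unknown joint distribution of real nodules — conclusions about real
data should rest on the statistical machinery, not on the simulator's
realism. The generator also makes no attempt at 3D partial-volume
effects, scanner noise spectra, or vascular/bronchial structures.

## Regions of interest and features

Contours are closed simple polygons in continuous 0-based (row, col)
pixel coordinates; integer coordinates are pixel centers.
`rasterize()` includes a pixel iff its center lies inside the polygon
under the even-odd rule; centers that graze the boundary exactly are
resolved by nudging the query point by `1e-9` px in both axes — an
arbitrary but fixed convention that makes the rule deterministic and
resolution-convergent (mask area converges to polygon area as spacing
shrinks, a property the tests check on disks at three scales).
Anisotropic spacing is carried through the containers; the generator
emits isotropic pixels, and every feature except the sigmoid slope is
spacing-agnostic.

From the whole-nodule and solid-portion pixel samples the package
computes:

* **Moments** — mean, sample SD (n−1), skewness `m3 / m2^(3/2)` and
  excess kurtosis `m4 / m2^2 - 3` with central moments on an n
  denominator. These moment (population) estimators are the default; the
  small-sample adjusted coefficients are available via
  `type = "adjusted"` and differ by O(1/n). Zero-variance samples get
  `NA` with an explicit flag, never a fabricated 0.
* **Percentile CT numbers** at 5/10/25/50/75/95 using linear
  interpolation at `h = (n-1)p/100` (quantile type 7). The convention is
  fixed because the original analysis software never states one.
* **Attenuation ratio** of whole-nodule mean to solid-portion mean,
  computed per nodule (group summaries are means of per-nodule ratios —
  the published group ratio 4.04 exceeds the ratio of group means, which
  is only ~3.0, confirming per-nodule averaging). Solid means within
  50 HU of zero make the ratio numerically unstable, so such nodules are
  flagged undefined and excluded from group averages and from model
  predictor sets.
* **Sigmoid fitting slope** — at each ~1-px arc-length boundary sample
  of the whole-nodule contour, the gray-level profile is read by
  bilinear interpolation at 0.25-px steps along the outward normal over
  +/-3 mm, and fit with `S(x) = a + b / (1 + exp(-(x - c)/w))`
  (free `a, b, c, w`; endpoints/midpoint initialization; `w` bounded
  below at 1e-3 to keep the fit identified). The per-profile slope is
  the sigmoid's maximal derivative `|b|/(4w)` in HU/mm and the nodule
  slope is the mean over converged profiles. The published values
  (~1.1, dimensionless-looking) imply a normalization that is never
  defined, so the package reports both the raw HU/mm slope and a
  variant normalized by the whole-nodule inter-quartile HU range, and
  no calibration target uses the feature. Profiles whose window leaves
  the image are skipped; if fewer than half of the attempted profiles
  converge the feature is flagged unreliable.

## The statistical pipeline

`run_model_comparison()` reproduces the analysis chain:

1. **One nodule per patient**, selected uniformly at random with an
   explicit seed, before any statistics — the within-patient correlation
   control.
2. **Univariate screening** at `alpha = 0.05`: Welch's t test for
   continuous predictors, Pearson chi-square (no continuity correction)
   for binary ones, switching to the Fisher exact test whenever an
   expected cell is below 5. The Fisher two-sided p-value is the
   point-probability sum (the doubling alternative exists in other
   software; the point-probability method is the one implemented and
   tested against full enumeration).
3. **One enter-method logistic model per predictor set** —
   clinical+CT, texture, and their union. The original description of
   "5 iterative entries of variables" is ambiguous; this package fits a
   single model per set with all screened variables entered
   simultaneously, which is the reproducible reading of the enter
   method. When both the raw eosinophil count and the derived
   eosinophilia flag survive screening, only the flag enters (they carry
   the same information; the flag is the published model's term).
   Continuous predictors enter untransformed, matching per-unit odds
   ratios. The fit is maximum likelihood by IRLS on internally
   standardized predictors with step-halving; convergence is a
   max-absolute-score below 1e-8; Wald standard errors come from the
   inverse observed information; quasi-complete separation (diverging
   standardized coefficients) is flagged, in which case odds ratios and
   p-values are withheld while the linear predictor remains usable for
   ranking.
4. **C-statistics** from in-sample predicted probabilities — the
   apparent original procedure; an optional k-fold cross-validated AUC
   (`cv_folds`) is offered as the honest complement, since in-sample
   AUCs of richer models are optimistically biased by construction.
   AUC is the Mann-Whitney estimator with ties counted one half;
   variances, covariances and the pairwise two-sided z-tests between the
   three correlated AUCs use the DeLong structural components. A zero
   variance of an AUC difference (rank-identical scores) returns p = 1
   with a degeneracy flag rather than 0/0. Wald CIs throughout;
   profile-likelihood CIs and any multiple-testing correction are out of
   scope, mirroring the original analysis.

## Numerical and testing choices

Every statistic has an independent oracle in the test suite: direct
summation loops for moments and percentiles, quadrature of the t density
for Welch p-values, the closed-form 2x2 chi-square, hypergeometric
enumeration for Fisher, exhaustive pair counting for AUC, a stratified
bootstrap for the DeLong variances, the closed-form 2x2 odds ratio and a
500-replicate coverage simulation for the logistic fit, and `glm`/`pROC`
as external cross-checks. Problem sizes in the routine suite (60–200
nodules per generated group, 200 cohort seeds for the model-ordering
property, 2000 bootstrap replicates) were chosen so the whole suite runs
in a few minutes on one core while keeping Monte-Carlo error far from
the asserted tolerances.

Determinism is end to end: one master seed drives every stage through
`derive_seed()` substreams, cohorts are reproducible bitwise (the tests
compare md5 hashes of twice-written cohorts), and pipeline manifests
contain content hashes but no wall-clock data, so identical configs
yield identical artifacts.

## Known limitations

* The simulator reproduces group-level marginal statistics, not the
  joint feature distribution of real PSNs; model AUCs on synthetic
  cohorts are typically higher than the published ones because the
  synthetic groups are cleanly separated in feature space. The package
  therefore asserts only the *ordering* of model performances, never the
  published AUC values.
* The sigmoid-slope normalization is a package definition, not a
  validated reconstruction of the original (undefined) one.
* Manual segmentation variability, 3D acquisition effects and scanner
  differences are outside the model.
* DICOM support is read-only and restricted to single-frame monochrome
  explicit-VR little-endian files with 16 bits allocated — enough to
  ingest exported thin-section slices, not a general DICOM stack.
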