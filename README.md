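# psntexture

Texture analysis for discriminating **transient** from **persistent
part-solid lung nodules (PSNs)** on thin-section CT.

Incidentally detected PSNs — nodules combining ground-glass haze with a
solid core — are a clinical dilemma: roughly half are transient
inflammatory lesions that vanish within about three months, while the
persistent ones carry a high probability of lung adenocarcinoma.
`psntexture` implements a quantitative discrimination pipeline built on
first-order histogram texture features of the nodule's Hounsfield-unit
(HU) pixel distribution, and a calibrated synthetic-cohort generator
that makes the entire pipeline testable without access to patient
images.

## What the package computes

For a nodule with a whole-nodule contour and an inner solid-portion
contour on one CT slice, the texture feature vector is

* mean attenuation and pixel SD of each region (HU),
* skewness `g1 = m3 / m2^(3/2)` and excess kurtosis
  `g2 = m4 / m2^2 - 3` of the HU histogram,
* percentile CT numbers at 5/10/25/50/75/95 (linear interpolation at
  `h = (n-1)p/100`),
* the whole-to-solid attenuation ratio (per nodule), and
* the sigmoid fitting slope of the margin: profiles along outward
  boundary normals fit with `S(x) = a + b/(1 + exp(-(x - c)/w))`, slope
  `|b|/(4w)` in HU/mm, averaged over boundary points.

The statistical stage mirrors the clinical study design: one nodule is
selected per patient; candidate predictors are screened univariately
(Welch t, Pearson chi-square, Fisher exact at expected counts < 5);
enter-method logistic models are fit for three predictor sets —
clinical+CT, texture, combined — by IRLS with Wald odds ratios; and the
three in-sample C-statistics (AUCs) are compared pairwise with the
DeLong test for correlated ROC curves.

The synthetic generator draws each nodule as a blurred two-component
disk phantom (ground-glass annulus + solid core on an aerated-lung
background) and is *calibrated* — via derivative-free search through the
full image-to-feature path — so that group means of extracted mean
attenuation, SD, skewness and 5th-percentile CT number reproduce the
published group statistics for transient and persistent PSNs
(`psn_table_targets()`, `psn_preset()`).

## Worked example

```r
library(psntexture)

## one synthetic transient-type nodule, texture features end to end
nod <- generate_nodule_image(psn_preset("transient")$image,
                             diameter_mm = 17, solid_frac = 0.4, seed = 7)
nod$image
#> <ct_slice> n1: 73 x 73 px, 0.7 x 0.7 mm/px, HU [-984, 569]

tf <- extract_all(nod$image, nod$annotation)
sprintf("whole mean %.1f HU, SD %.1f, skewness %.3f, 5th pct %.1f HU",
        tf$whole_mean, tf$whole_sd, tf$whole_skewness, tf$whole_pctl[["p5"]])
#> "whole mean -598.8 HU, SD 188.8, skewness 1.377, 5th pct -836.4 HU"
```

The low mean attenuation, strongly positive skewness and deep 5th
percentile are the transient signature: an ill-defined margin lets
lung-density pixels into the nodule rim, piling mass on the left of the
HU histogram while the solid core keeps a long right tail.

```r
## full study-scale cohort (39 transient / 47 persistent nodules)
co     <- generate_cohort(39, 47, seed = 2026)
feats  <- extract_cohort_features(co)
merged <- merge(co$table, feats[, setdiff(names(feats), "patient_id")],
                by = "nodule_id")
run_model_comparison(merged, seed = 2026)
#> <psn_model_comparison> 56 patients (21 transient / 35 persistent), alpha = 0.05
#>   AUC clinical_ct  0.935 (95% CI 0.852, 1.000)  [age, smoker, wbc, ...]
#>   AUC texture      1.000 (95% CI 1.000, 1.000)  [whole_mean, whole_skewness, ...]
#>   AUC combined     1.000 (95% CI 1.000, 1.000)  [age, smoker, ..., whole_mean, ...]
#>   DeLong pairwise:
#>     combined vs clinical_ct: dAUC +0.065, p = 0.12
#>     combined vs texture: dAUC +0.000, p = 1
#>     texture vs clinical_ct: dAUC +0.065, p = 0.12
```

The AUC ordering — texture-augmented models dominating the clinical+CT
model — is the qualitative conclusion the pipeline supports; absolute
synthetic AUCs run higher than on real patients because the calibrated
groups are cleanly separated in feature space (see the methods
vignette).

A disk-based pipeline with the same stages is available through
`psn_config()` + `psn_simulate()` / `psn_extract()` / `psn_analyze()` /
`psn_run_all()`, or from a shell via the thin CLI at
`inst/cli/psntexture` (subcommands `simulate`, `extract`, `analyze`,
`all`).

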