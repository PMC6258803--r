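---
title: "BMI-based size-specific dose estimation: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{BMI-based size-specific dose estimation: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmissde)
```

## The estimation chain

The scanner-reported CTDI~vol~ is normalised to a 32-cm acrylic phantom; the
size-specific dose estimate rescales it to the patient:

$$\mathrm{SSDE} = f(D_E)\cdot \mathrm{CTDI_{vol}}, \qquad
  D_E = \sqrt{D_{AP}\cdot D_{LAT}},$$

with $f$ the size-dependent conversion factor. When the skin-to-skin
diameters have not been measured, the effective diameter is estimated from
BMI through an affine regression fitted on an adult abdominal cohort:

$$\hat D_E = 0.76\,\mathrm{BMI} + 9.4 \quad [\mathrm{cm}],$$

valid for BMI 17.4–38.8 kg/m² (the fitted cohort's range). The package
evaluates the line for any positive BMI — the conversion table deliberately
spans BMI 15–50 — but flags values outside the validity range as
extrapolations. A companion fat-distribution metric, the ratio
$D_{RATIO} = D_E / D_{IN}$ of the outer to the inner (subcutaneous-fat
excluded) effective diameter, is supported as a descriptive covariate; it is
a poor dose predictor and plays no role in the SSDE chain.

## Calibrating the conversion curve

Reference conversion factors are published as a lookup table indexed by
effective diameter. Rather than hard-coding coefficients from an external
document, the package ships the 36-row BMI-indexed table for the 32-cm body
phantom and recovers the curve from it, keeping the artifact self-contained
and re-calibratable from any user-supplied table:

$$f(d) = a\,e^{-b d}, \qquad
  \ln f \sim \textrm{OLS on } d \;\Rightarrow\; b = -\text{slope},\;
  a = e^{\text{intercept}}.$$

Log-linear least squares is exact for noiseless exponential data,
closed-form and deterministic; the only noise in the table is 2-decimal
rounding (≤ 0.005), so weighting subtleties are immaterial at the 0.01
tolerance we hold the calibration to.

```{r}
m <- default_conversion_model()
m
```

The two-parameter curve explains all 36 printed rows to within 0.006
(leave-one-out: 0.007) — a genuine goodness-of-fit statement, since 36
(diameter, factor) pairs are reduced to two coefficients. One consequence of
refitting from rounded data: the regenerated table reproduces every printed
factor within ±0.01 but not always to the last printed digit (the BMI-15 row
lands at 1.72 against the printed 1.73).

Conversion factors are always evaluated at the *unrounded* regression
diameter; rounding (diameter to 1 decimal, factor to 2, ties away from zero)
happens only when a table is presented. There is deliberately no default
16-cm (head-phantom) model: no calibration rows for it are packaged, and
fabricating coefficients would be worse than refusing, so a 16-cm model must
be fitted from user-supplied rows.

## The synthetic cohort generator

No per-patient data are deposited for the study population, so validation
runs on a simulator designed to reproduce its published joint structure.
One integer seed governs all draws, in a fixed documented order.

1. **BMI** is drawn from a truncated normal on [15, 50] kg/m². The published
   moments (24.6 ± 4.8) describe the *observed* cohort, so the generator
   solves for the parent mean and SD whose truncated distribution has
   exactly those moments (parent ≈ N(24.11, 5.27²)). Naive truncation of
   N(24.6, 4.8²) would shrink the realized SD to ≈ 4.5 and weaken every
   BMI-driven correlation downstream, including the headline r(BMI, D_E).
2. **Effective diameter** is the regression plus Gaussian noise, floored at
   12 cm (below any plausible adult abdomen). The noise SD is not guessed:
   for an affine-plus-noise model,
   $r = \left(1 + \sigma^2/(\beta\,\mathrm{sd}_{BMI})^2\right)^{-1/2}$, so
   the published $r = 0.88$ implies
   $\sigma = 0.76 \cdot 4.8 \sqrt{1/0.88^2 - 1} = 1.969$ cm
   (`calibrate_de_noise()`). The implied diameter SD,
   $\sqrt{(0.76\cdot4.8)^2 + 1.969^2} = 4.15$ cm, matches the published
   27.8 ± 4.1 cm without further tuning.
3. **AP/lateral split.** With $s \sim N(\mu_s + c\,z_{\log D_E},\, w^2)$ and
   $D_{AP} = D_E e^{-s}$, $D_{LAT} = D_E e^{s}$, the geometric-mean identity
   holds *exactly* by construction and both diameters stay positive.
   $\mu_s$ is half the log of the typical lateral/AP ratio (31.5/24.8). The
   spread $w$ and coupling $c$ are calibrated by least squares against the
   three published pairwise diameter correlations (0.78, 0.96, 0.92) using
   the closed-form log-scale correlation algebra of the model
   (`calibrate_aspect_params()`); a two-parameter family cannot hit three
   targets exactly, and the achieved values (0.779, 0.962, 0.921, max
   residual 0.002 on the log scale; raw-scale Pearson runs ≈ 0.01 lower)
   are returned rather than hidden. The calibrated defaults are
   $w = 0.0507$, $c = -0.0289$ — the negative coupling reflects that the
   published AP–D_E correlation exceeds the lateral one, i.e. larger
   patients are relatively rounder.
4. **Diameter ratio** is normal about 1.23 ± 0.13 with a loading of
   0.48 SD-of-BMI (its published correlation with BMI), truncated at 1.01;
   its correlations with dose emerge rather than being calibrated.
5. **Scanner output** uses the standard attenuation-driven
   tube-current-modulation proxy: CTDI~vol~ grows exponentially with
   diameter, $5.5\,e^{0.14 (D_E - 27.8)}$ mGy with 15% multiplicative noise,
   clipped to [2, 30] mGy to abstract the tube-current limits. No
   per-patient tube-current data are published, so only the two BMI-group
   means (4.33 and 9.68 mGy for BMI < 25 / ≥ 25) constrain the growth rate;
   0.14 cm⁻¹ reproduces both within a few percent and the package holds
   itself only to a loose ±20% band on them.
6. **Scan length** is normal, 47.5 ± 4 cm (the published DLP/CTDI~vol~
   ratios imply ≈ 47–49 cm; the SD is a plausibility choice). DLP,
   conversion factor and SSDE are then derived through the dose model, so
   every row satisfies its defining formula identically.

What the simulator does *not* emulate: sex and age structure (no published
formula uses them), the 16-cm phantom pathway, effective dose (requires a
proprietary organ-dose calculator), measurement error in the calliper
diameters, and the exact dose distributions of the real cohort — passing
tests therefore demonstrate the pipeline's internal consistency and its
faithfulness to the published correlation structure, not agreement with any
individual scanner's output.

```{r}
cohort <- generate_cohort(cohort_params(n = 5000, seed = 7))
pearson(cohort$bmi, cohort$d_e_cm)
```

## Statistics layer

`pearson()`, `ols()` and `welch_two_sample()` wrap the corresponding base R
machinery behind validated interfaces (equal lengths, n ≥ 3, non-constant
input) and are cross-checked in the test suite against brute-force summation
oracles. Welch's unequal-variance form was chosen for the BMI-group
contrasts because dose SDs in the two groups differ several-fold, which
makes the pooled-variance assumption untenable; p-values are stored at full
precision and only truncated at presentation. No multiple-testing correction
is applied, matching the analysis the layer emulates.
`build_validation_report()` assembles the cohort summary (overall and per
BMI category), the full 8-variable correlation matrix with two-tailed
p-values, the D_E-on-BMI refit and the group contrasts into a JSON-ready
object.

## Numerical choices and edge cases

* Validation failures raise a classed condition
  (`bmissde_validation_error`); the CLI maps it to exit code 2 and keeps
  stdout clean for data.
* Presentation rounding is half-away-from-zero with a 1e-9 nudge so decimal
  halves stored just below their binary representation still round up;
  internal computation never rounds.
* Truncated-normal sampling is inverse-CDF, so exactly `n` uniforms are
  consumed and cohorts are reproducible; changing `n` changes all draws (no
  stream-splitting guarantee across cohort sizes).
* `calibrate_aspect_params()` estimates Var(log D_E) from a large internal
  sample (n = 200 000) under a fixed private seed, so calibration is
  repeatable and independent of the caller's RNG state; the optimiser is a
  coarse grid followed by Nelder–Mead on the closed-form objective.
* Degenerate configurations fail fast: a BMI SD unattainable inside the
  truncation window, a ratio loading exceeding the total ratio SD, or
  a non-increasing clip interval are all rejected at `cohort_params()` time.

## Problem sizes

The shipped checks use cohorts of 5000 for correlation-level comparisons
(sampling error on r is ≈ 0.004 there) and 100 000 for parameter-recovery
checks (slope recovered within ±0.01); both run in seconds.

## Known limitations

The regression and conversion table are specific to adult abdominal CT at
120 kVp on a 32-cm phantom; the BMI route estimates the diameter of a
*typical* patient of that BMI, so individuals with atypical fat distribution
are better served by measured diameters (which the CLI prefers whenever both
inputs are given). SSDE itself estimates the mean dose at the centre of the
scan volume with a stated 10–20% uncertainty even when size is known; it is
not organ dose, and this package deliberately computes no effective dose.
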