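---
title: "Hjorth descriptors for 2D textures: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hjorth descriptors for 2D textures: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hjorth2d)
```

## The model

Hjorth's three parameters summarize a zero-mean signal through the
variances of the signal and its derivatives. In one dimension they have
a spectral reading: Activity is the total power (zeroth spectral
moment), Mobility the square root of the normalized second moment (a
mean-frequency proxy), and Complexity a normalized fourth-moment ratio
(a bandwidth proxy). `hjorth2d` carries the definitions to images by
replacing the directional derivative with non-directional derivative
*magnitudes*,

$$I' = \sqrt{\left(\tfrac{\partial I}{\partial x}\right)^2 +
             \left(\tfrac{\partial I}{\partial y}\right)^2},\qquad
  I'' = \sqrt{\left(\tfrac{\partial^2 I}{\partial x^2}\right)^2 +
              \left(\tfrac{\partial^2 I}{\partial y^2}\right)^2},$$

(pure partials only — no mixed term) and defining

$$\mathrm{Activity} = \sigma_I^2,\qquad
  \mathrm{Mobility} = \frac{\sigma_{I'}}{\sigma_I},\qquad
  \mathrm{Complexity} = \frac{\sigma_{I''}/\sigma_{I'}}
                              {\sigma_{I'}/\sigma_I},$$

with population (divide-by-N) standard deviations over all pixels.
Because $I'$ and $I''$ are non-negative magnitude fields, the exact 1D
spectral identities no longer hold (a pure plane wave does not have
Complexity exactly 1 in 2D); what survives, and what the test suite
checks, are the qualitative orderings — Mobility increases with spatial
frequency, smoother random fields have lower Mobility — and the
Parseval identity for Activity, which `spectral_total_power()` verifies
to 1e-9 relative as an independent frequency-domain route.

The extraction pipeline (`hjorth_descriptors()`) is: grayscale
conversion → min–max normalization to $[0,1]$ → smoothing → derivative
magnitudes → descriptors. Descriptors are computed per whole image; no
tiling. The unit of analysis this emulates is a single 256 × 256, 8-bit
pollen micrograph, but any size ≥ 3 × 3 is accepted.

## Tunable parameters

* **Grayscale weights** (`grayscale_weights`, default BT.601
  `0.299, 0.587, 0.114`): the `rgb2gray` convention of the MATLAB-family
  environments this methodology originated in. Dimensionless;
  configurable.
* **Smoothing** (`smoothing_spec()`, default 3 × 3 unit-sum box,
  replicate borders): a pre-derivative low-pass, needed because the
  difference stencils amplify pixel noise. The source methodology
  describes an "average filter" whose coefficients depend on the image
  mean and standard deviation but does not give the formula; we did not
  guess it. The default is the plain unit-sum box; a Gaussian
  (`sigma` in pixels, default `0.3((w-1)/2 - 1) + 0.8`) is provided, and
  `pipeline_config(kernel_fn = ...)` accepts any image-adaptive unit-sum
  kernel so the original rule can be slotted in if it is ever
  clarified.
* **Derivative scheme** (`scheme`, default `"central"`): central
  differences `(f[i+1] - f[i-1])/2` and `f[i+1] - 2f[i] + f[i-1]`,
  exact on linear/quadratic ramps, matching the default gradient
  convention of the same environments; `"sobel"` offers the smoothed
  stencil. Borders use one-sided first differences and replicated
  second differences.
* **Border inclusion** (`crop_border`, default 0): the descriptor
  definitions are global over the image, so frame rows and columns are
  *included* in the variances by default; cropping would be an
  undocumented alteration of the method. `crop_border = n` strips an
  n-pixel frame from the image and both derivative fields before the
  variance step, for sensitivity checks (the plane-wave
  frequency-response test uses `crop_border = 2` to remove the
  one-sided-stencil frame).
* **`compute_on`** (default `"filtered"`): descriptors come from the
  normalized *and smoothed* image, the stated processing order;
  `"unfiltered"` skips smoothing for comparison.
* **Levene centring** (`center`, default `"mean"`): classic Levene, the
  default of the statistics packages whose output layout the reported
  tables follow; `"median"` gives Brown–Forsythe.
* **Tie handling**: mid-ranks throughout; `kruskal_wallis()` applies
  the standard correction `1 - Σ(t³-t)/(N³-N)`. The published
  three-group H values reproduce from their printed integer rank sums
  with *no* tie correction (descriptor values are continuous), so
  `kruskal_wallis_from_ranks()` defaults to a correction factor of 1.

## Statistical procedure

`compare_groups()` mirrors the small-cohort workflow: per descriptor,
Shapiro–Wilk normality per group and Levene's variance-homogeneity test
document that the parametric ANOVA assumptions fail (as they do on the
real pollen cohorts), then the Kruskal–Wallis rank ANOVA provides the
global test and Dunn's z-tests on rank means, Bonferroni-corrected by
the `k(k-1)/2` pairs, identify the responsible pairs.

The post hoc method deserves a note: the source tables never name the
multiple-comparison procedure used. Dunn's z-test with Bonferroni
correction was selected because it reproduces *every* published
pairwise adjusted p-value (six significant and three non-significant)
from the published rank sums to better than 1e-6 — the reconstruction
is the identification, and the test suite pins all nine values.

For very small cohorts the χ² reference for H is approximate;
`kruskal_wallis(..., method = "permutation")` enumerates all distinct
group assignments (capped near 200k) and is exact by construction. The
suite compares the two on a 2+2+2 toy case against a full 6!
enumeration.

## The synthetic generator

Real pollen micrograph databases are rarely redistributable, so
cohort-level behaviour is exercised on seeded synthetic textures
(`make_cohort()`):

* `plane_wave`: analytic sinusoids for closed-form and
  frequency-response checks.
* `gaussian_random_field`: white Gaussian noise spectrally shaped by
  $|\omega|^{-\beta/2}$ (power slope $-\beta$), standardized to a target
  amplitude. $\beta$ controls texture coarseness, which is exactly the
  second-order structure the descriptors respond to; the generator's
  periodogram slope recovers $\beta$ to ±0.3 (tested).

The emulated study design — three groups of sizes 18/8/9, 256 × 256
8-bit images, written as min–max scaled PNG — reproduces the cohort
geometry of the pollen comparison with group separation driven by
spectral exponents 0/1/2. What the generator does **not** emulate:
pollen morphology, optical artefacts (overexposure, blur, graininess),
staining variation, or within-taxon biological variance structure. A
green cohort test therefore establishes that the pipeline detects
controlled second-order texture differences at the study's sample
sizes — not that the descriptors separate real taxa, which only the
original image database could show.

Per-image seeds are a stable polynomial hash of
`(master_seed, label, index)` mod $2^{31}-1$, so adding a group never
reshuffles existing groups' images and any manifest regenerates its
cohort exactly.

## Numerical choices and degenerate inputs

* Population (1/N) variance everywhere. Mobility and Complexity are
  ratios, so the N vs N−1 choice cancels there; it only shifts
  Activity's absolute scale, which is reported as the raw variance of
  normalized intensities (no image-size normalization).
* Min–max normalization clamps last-place rounding so the output range
  is exactly $[0,1]$; a constant image raises a classed
  degenerate-input error rather than producing NaN, and that error
  propagates out of `hjorth_descriptors()` with the stage name
  attached.
* Mobility of a constant image and Complexity of an image with constant
  gradient field (e.g. a linear ramp after a 1-pixel crop) are
  undefined and error explicitly.
* Oracle tolerances: the vectorized pipeline is held to 1e-10 relative
  against a straight-line loop reimplementation; derivative fields to
  1e-12 against a dense finite-difference oracle; Parseval to 1e-9
  relative (FFT rounding).
* 8-bit PNG output quantizes; oracle-grade tests therefore run on
  in-memory float images, and the disk round-trip is tested separately.

## Limitations

* TIFF input is unavailable in this build (no TIFF reader among the
  supported dependencies); PNG, JPEG and netpbm are supported.
* The mean/sd-dependent coefficient rule of the original average filter
  is unpublished; until clarified, results are conditional on the box
  (or user-supplied) kernel.
* The published per-cohort descriptor values (normality/Levene table
  entries) depend on the original 35 images and cannot be reproduced
  here; only the rank-statistics tables, which are fully determined by
  the printed rank sums, are pinned numerically.
* The nearest-centroid classifier is exploratory plumbing for the
  workflow's final stage; the scientific surface of the package is the
  descriptor extraction and the rank statistics.
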