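---
title: "Quantifying thyroid-nodule echogenicity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying thyroid-nodule echogenicity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echoquant)
```

## The measurement model

On a B-mode sonogram, echogenicity is displayed brightness: tissue that
scatters more ultrasound energy back to the transducer is rendered with
higher gray values. `echoquant` treats the displayed 8-bit gray level as
the measurand and summarises a region by its arithmetic mean. No attempt
is made to invert the scanner's log-compression or time-gain compensation:
the indices are defined on the displayed image, which is also what a
clinician judges. Because absolute display brightness depends on machine
settings, the useful quantities are *relative*: differences against
reference tissues in the same frame (thyroid parenchyma, strap muscle), or
a ratio against an automatically selected reference.

Four indices are computed per nodule:

* `EI_N` — the trimmed mean gray level of the nodule;
* `EI_N-T = EI_N − μ_thyroid` — negative values define quantitative
  hypoechogenicity;
* `EI_N-M = EI_N − μ_muscle` — negative values define quantitative marked
  hypoechogenicity (strap muscle is normally the darkest reference
  tissue, so this is the stricter criterion);
* `EI_(N-R)/R = (EI_N − μ_ref)/μ_ref` — the automatic index; being a
  ratio, it is invariant under linear rescaling of display brightness,
  which `EI_N-T`/`EI_N-M` are not.

The classification rule is strict: `EI_N-M < 0` → marked hypoechogenicity,
else `EI_N-T < 0` → hypoechogenicity, else iso-/hyperechoic. A nodule
whose deciding comparator is unavailable is labelled undetermined rather
than guessed.

## Coordinates, rasterization and region input

All coordinates are `(row, col)`, 0-based, origin top-left, so "above"
(anterior — toward the transducer) always means a smaller row index. Region
outlines arrive as JSON polygons in pixel-center units: the center of
pixel `(i, j)` is the point `(i, j)`. A pixel belongs to a region iff its
center lies inside the polygon under the even-odd rule; centers exactly on
the boundary are resolved half-open (top/left inclusive), so abutting
polygons tile the grid without overlap or double counting. Polygons must
be simple; self-intersecting outlines are rejected rather than silently
interpreted. The rasterizer is verified against a brute-force containment
test at every pixel center on randomly generated polygons.

Images are 8-bit grayscale PNG or single-frame DICOM. Color PNGs are
converted by BT.601 luminance (round half up). `MONOCHROME1` DICOMs are
inverted on load so that larger always means brighter; multi-frame files
and bit depths other than 8 are refused rather than approximated.

## Outlier trimming

Cystic (anechoic) areas and calcifications (hyperechoic foci) inside a
nodule reflect structure, not tissue echogenicity, and are removed before
the nodule mean is taken. Two policies are provided (`trim_policy()`):

* **fence** (default): zero-valued pixels are always anechoic (zero marks
  the outside of the imaging field or pure fluid); robust Tukey fences are
  then computed on the *non-zero* gray values (type-7 quartiles), and a
  pixel is removed when strictly below `Q1 − 1.5·IQR` or strictly above
  `Q3 + 1.5·IQR`. Strict comparisons guarantee a constant region is never
  trimmed.
* **absolute**: fixed clinical cut-offs, anechoic `≤ 5` and hyperechoic
  `≥ 250` (both configurable).
* **none**: no trimming; appropriate for continuous-valued test images and
  for phantoms known to contain no cyst or calcification.

A known limitation of the fence rule: a cyst whose pixels sit at 1–2 gray
units (rather than exactly 0) escapes the fence when the solid tissue's
IQR is wide, because `Q1 − 1.5·IQR` then falls below zero. The absolute
policy handles such near-zero cysts and is the better choice when the
anechoic level is known. Thyroid and muscle reference means are always
raw, untrimmed means — trimming is a nodule-specific correction.

## The automatic reference

The anterior region is defined as all pixels outside the contoured nodule
with row index strictly less than the nodule center row. The center is the
row centroid of the rasterized nodule mask by default (`center =
"centroid"`); a bounding-box midpoint is available as an option. The
region spans the full image width by default; `lateral = "nodule-width"`
restricts it to the nodule's column range for narrow fields of view. With
`L` the mean of the non-zero anterior gray values, the outside reference
is every anterior pixel with `0 < GR < L` — strict at both ends, since
zeros carry no echo information and `L` itself must exceed every reference
pixel. This biases the reference toward the darker anterior structures,
i.e. the strap muscles. `μ_ref < L` holds by construction whenever a
reference exists; a constant image has no pixel strictly below its
anterior mean, so no reference — `analyze_image()` reports the automatic
index as `NA` in that case instead of failing the whole analysis.

The entire chain is property-tested against an independent brute-force
implementation written directly from the definitions, on hundreds of
random small images.

## The phantom generator

`make_phantom()` emulates the gross anatomy of a transverse neck sonogram:
a strap-muscle band at the top of the frame, a thyroid-parenchyma band
below it, and an elliptical nodule embedded lower in the parenchyma. Pixel
values are `round(clip(μ_region · G))` with `G` a unit-mean gamma
multiplier — multiplicative, right-skewed, variance proportional to the
squared mean, a standard surrogate for log-compressed speckle texture. The
default shape parameter 4 gives a speckle coefficient of variation of 0.5.
Default region means (muscle 18.59, thyroid 41.31, nodule 25) are typical
display levels for these tissues on a linear-probe thyroid exam. Optional
anechoic cyst disks (gray 0–2, a configurable fraction of the nodule area)
and hyperechoic foci (gray 250–255) exercise the trimming step with known
counts.

What the phantom does *not* model: beam-forming and point-spread
correlation (its speckle is pixel-independent), attenuation with depth,
shadowing and enhancement artifacts, or the skin line. Passing the phantom
recovery tests therefore demonstrates that the estimator chain is
unbiased on stationary multiplicative speckle with known region means — it
does not certify performance on clinical images, where region outlining
and machine settings dominate.

Recovery is tested on cyst-free phantoms with trimming disabled, because
on pure speckle every pixel is legitimate signal: with fence trimming the
asymmetric right tail of the gamma texture would be clipped, biasing
`EI_N` downward by design rather than by error. The configured
`EI_N-T`/`EI_N-M` are recovered within three standard errors (computed
from the empirical region variances) on 100 seeded phantoms at 256×256;
empirical region means converge to the configured levels as the canvas
grows (checked at 64, 128 and 256). The phantom's implied automatic index
is approximated as `(μ_nodule − μ_muscle)/μ_muscle`; the actual `μ_ref`
mixes muscle with dark thyroid/background speckle, so tests of
`EI_(N-R)/R` against phantom truth are qualitative (sign and scaling
behavior), not exact.

`make_cohort()` draws tabular nodule records instead of images: per-class
normal EI distributions and Bernoulli binary features, with defaults
encoding a 411-nodule population (254 benign / 157 malignant, benign
`EI_N-T` at −1.64 ± 18.44 vs malignant −13.65 ± 14.88, and so on). The
normal model is a deliberate simplification — real per-class EI
distributions are skewed, so the cohort's implied operating points differ
from published ones by a few percentage points; cohort-level tests
therefore compare against the generator's analytic values and only
qualitatively (AUC above chance, monotone quartile trend) against the
published study behavior.

## Statistical workflow

The diagnostics module wraps the standard 2×2 machinery with explicit,
tested definitions:

* metrics: `sens = TP/(TP+FN)` etc.; a zero denominator yields `NA`, never
  a silent 0;
* odds ratios: Woolf (log) confidence intervals,
  `exp(ln OR ± z·√(1/a+1/b+1/c+1/d))`; zero cells error by default, with
  Haldane's +0.5 correction opt-in;
* Fisher's exact test: two-sided p as the sum of hypergeometric
  probabilities not exceeding the observed table's (with the customary
  `1 + 1e-7` relative guard against floating-point ties), checked to
  1e-12 against full enumeration;
* Cohen's kappa with the conventional interpretation bins (0.21–0.40
  "fair", etc.);
* ROC/AUC in the Mann–Whitney pair form with ties counted ½; echogenicity
  indices use `direction = "lower_positive"` since darker nodules are the
  suspicious ones;
* logistic regression via `stats::glm` (IRLS) with Wald intervals;
  complete separation is flagged on the returned rows. On a single binary
  predictor the fitted beta equals the table's log odds ratio, which the
  tests assert to 1e-6;
* quartile risk groups split at type-7 quartiles (half-open, quantile in
  the upper group) with a chi-square test for trend
  (`stats::prop.trend.test`).

No multiplicity correction is applied anywhere; the workflow mirrors a
single pre-specified analysis, and adjusting is left to the user.
"Less-than-median" cut-offs are computed over the full supplied cohort
with the median itself in the test-negative group.

## Numerical conventions

All means and indices are computed in double precision with no
intermediate rounding; two-decimal values appear only in `print()`
methods. Fractional center rows are compared strictly (`row <
center_row`). Quantiles are type 7 unless configured otherwise. Errors are
classed conditions (`echoquant_degenerate_nodule`,
`echoquant_no_reference`, ...) so callers can distinguish degenerate
inputs from bugs; batch processing logs per-item failures and continues.

## Problem sizes in the test suite

The shipped tests generate everything programmatically: random rasters up
to 32×32 against brute-force oracles (≥ 200 instances across the
automatic-reference chain, Fisher's test and AUC), 100 phantoms at
256×256 for recovery, 200 simulated cohorts of n = 411 for the
cohort-level operating-point checks, and n = 2000 for multivariate
logistic parameter recovery. These sizes give comfortable statistical
resolution for every asserted tolerance while keeping the full suite
around half a minute.
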