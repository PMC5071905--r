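# echoquant

Quantitative echogenicity indices for thyroid-nodule B-mode ultrasound.

Hypoechogenicity — a nodule appearing darker than the surrounding thyroid
parenchyma — is one of the classic sonographic markers of thyroid
malignancy, but as a clinician-assessed category it suffers from
substantial inter-observer variability. `echoquant` replaces the
qualitative call with measurable gray-level indices computed from the
image itself, and ships the complete diagnostic-statistics workflow needed
to evaluate such indices against histological truth. It is intended for
researchers in quantitative ultrasound and computer-aided diagnosis.

## The indices

Given an 8-bit B-mode image and polygon outlines of the nodule, thyroid
parenchyma and strap muscle:

- **EI_N** = μ_nodule, the mean gray level of the nodule after removing
  anechoic pixels (cystic fluid) and hyperechoic foci (calcifications) as
  outliers;
- **EI_N-T** = μ_nodule − μ_thyroid and **EI_N-M** = μ_nodule − μ_muscle,
  the adjusted indices; EI_N-T < 0 is quantitative *hypoechogenicity*,
  EI_N-M < 0 quantitative *marked hypoechogenicity*;
- **EI_(N-R)/R** = (μ_nodule − μ_ref)/μ_ref, a fully automatic index that
  needs no manually outlined reference. The *anterior region* is everything
  outside the nodule and above its center (anatomically dominated by the
  strap muscles); with L the mean of its non-zero gray values, the outside
  reference is the set of anterior pixels with 0 < GR_ij < L, and μ_ref
  their mean.

The statistics module covers 2×2 diagnostic metrics
(sensitivity/specificity/PPV/NPV/accuracy), odds ratios with Woolf CIs,
Fisher's exact test, Cohen's kappa with interpretation bins, ROC/AUC
(Mann–Whitney form), uni-/multivariate logistic regression, and malignancy
prevalence by EI quartile. A phantom module synthesises speckle images and
nodule cohorts with known ground truth, so the whole chain is testable
without clinical data.

## Worked example

Analyse a synthetic phantom with a hypoechoic nodule (configured region
means: nodule 25, thyroid 41, muscle 19):

```r
library(echoquant)
ph  <- make_phantom(phantom_config(mu_nodule = 25, mu_thyroid = 41,
                                   mu_muscle = 19, seed = 5))
analyze_image(ph$image, ph$regions)
#> Echogenicity analysis
#>   EI_N        (nodule mean)     : 24.04
#>   EI_N-T      (vs thyroid)      : -16.95
#>   EI_N-M      (vs muscle)       : 5.20
#>   EI_(N-R)/R  (automatic)       : 0.0838
#>   mu_ref = 22.18, L = 36.60; trimmed 0 anechoic + 152 hyperechoic of 7238 px
#>   class: hypo
```

The nodule is darker than parenchyma (EI_N-T < 0 → hypoechoic) but
brighter than muscle (EI_N-M > 0 → not markedly hypoechoic), matching the
configured −16 / +6 differences up to speckle sampling noise.

Diagnostic statistics from a published 2×2 table (141/157 malignant and
173/254 benign nodules called hypoechoic by clinicians):

```r
tab <- contingency_table(141, 16, 173, 81)   # TP, FN, FP, TN
diagnostic_metrics(tab)
#> sens 0.8981  spec 0.3189  PPV 0.4490  NPV 0.8351  acc 0.5401
odds_ratio(tab)
#> OR 4.13 (beta 1.4173, 95% CI 2.31-7.37)
cohen_kappa(contingency_table(211, 103, 35, 62, orientation = "agreement"))
#> kappa 0.2505 (fair)
```

Sensitivity is high but specificity poor — most benign nodules are also
called hypoechoic — which is exactly the motivation for the quantitative
indices.

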