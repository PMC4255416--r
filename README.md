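# lesionvol

Quantifying subcortical white-matter hyperintensities and brain atrophy
from multimodal MRI, at desk scale and with exact ground truth.

## The problem

Subcortical hyperintensities (SH) — bright regions on proton-density (PD)
and T2-weighted MRI of the aging brain — are read as radiological signs of
small-vessel disease and have been linked to executive function, mental
processing speed and memory in Alzheimer's disease (AD) and normal aging.
Studying those links quantitatively requires a long chain of image
processing and statistics, and every stage of the chain can silently bias
the result. `lesionvol` is that chain as a tested R package, aimed at
method developers and students who need each link verifiable against known
truth:

1. **Synthetic data** — analytic multimodal brain phantoms (T1/PD/T2) with
   exact per-class ground-truth volumes, and synthetic AD/NC cohorts with
   known linear structure.
2. **Brain extraction** — supratentorial intracranial mask and ST-TIV
   (parenchyma + lesions + all CSF under the dura).
3. **Tissue segmentation** — localized four-Gaussian mixture fitting on T1
   yielding GM / WM / sulcal CSF, with ventricular CSF split off by
   3D flood fill from seed voxels.
4. **Lesion segmentation** — joint PD∧T2 z-thresholds over fitted WM
   statistics; connected components classified *periventricular* (pvSH)
   vs *deep white* (dwSH) by 3D connectivity to ventricular CSF; cystic
   lacunar cores extracted as CSF-intensity voxels on T1 inside SH.
5. **Parcellation** — a deterministic, plane-based 26-region volume-of-
   interest atlas (13 per hemisphere, including medial middle frontal and
   anterior/posterior temporal).
6. **Volumetrics** — per-subject profiles: raw cc per class per VOI,
   brain parenchymal fraction `BPF = 100·(GM+WM)/ST-TIV`, vCSF/ST-TIV,
   head-size normalization and reference z-scores (log transform when the
   reference skewness exceeds 1).
7. **Statistics** — normal-referenced cognitive composite z-scores,
   ANCOVA group contrasts, Cohen's *d* by the pooled-SD method
   `d = (m₁−m₂)/√(((n₁−1)s₁²+(n₂−1)s₂²)/(n₁+n₂−2))`, linear regression
   with backwards elimination of non-significant predictors (standardized
   β, partial R² = t²/(t²+df)), and the lobar-then-subregion stepwise VOI
   strategy (≤ 6 VOIs per model).

The methods vignette (`vignettes/lesionvol-methods.Rmd`) explains the
models, every tunable parameter, and the design decisions.

## Worked example

Segment a noisy phantom and compare with its ground truth:

```r
library(lesionvol)
spec <- defaultPhantomSpec(noiseSD = 3, seed = 1)  # 10% of the class gap
res  <- runPhantomPipeline(spec)
res$mask
#> IntracranialMask: 141376 voxels, ST-TIV = 1131.0 cc
res$profile
#> VolumetricProfile 'phantom': ST-TIV 1131.0 cc, BPF 80.9%, vCSF/ST-TIV 0.0095
componentTable(res$lesions)
#>   id  class voxels volume_cc       cx       cy       cz parent
#> 1  1   pvSH    556     4.448 48.11032 46.36833 36.52313     NA
#> 2  2   pvSH    188     1.504 24.97872 49.22340 35.50000     NA
#> 3  3   dwSH     75     0.600 52.48000 34.45333 34.86667     NA
#> 4  4 lacune      6     0.048 48.33333 46.33333 36.50000      1
round(diceByClass(res$labels, res$phantom$truth), 3)
#>   sCSF   vCSF     GM     WM   pvSH   dwSH lacune
#>  1.000  0.913  0.995  1.000  1.000  1.000  1.000
```

The phantom carried 6.0 cc of periventricular load (one 4.5 cc and one
1.5 cc lesion; 0.048 cc of the former re-labeled as its lacune core), a
0.6 cc deep lesion, and a brain of analytic volume 1132 cc — all recovered
within a voxel at this noise level, with per-class Dice ≥ 0.91.

Recover a planted brain–behavior effect in a synthetic AD cohort
(a standardized coefficient of 0.17 from periventricular lesion load to a
speed composite, alongside an age effect of −0.33):

```r
g1  <- function(m, s) matrix(c(m, s), 2, dimnames = list(c("mean", "sd"), "AD"))
ln1 <- function(med, iqr) { m <- g1(med, iqr); attr(m, "lognormal") <- TRUE; m }
spec <- cohortSpec(
  nPerGroup = c(AD = 265L),
  meanSD = list(age = g1(72.8, 9.0), sex = g1(0.57, NA),
                education = g1(13.8, 3.8), pvsh_cc = ln1(4.5, 9.9)),
  effectStructure = data.frame(outcome = "speed",
                               predictor = c("pvsh_cc", "age"),
                               beta = c(0.17, -0.33)),
  noiseSD = c(speed = sqrt(1 - 0.17^2 - 0.33^2)), seed = 5L)
co <- generateCohort(spec)
co$st_tiv <- 1200
nz <- normalizeAndZscore(co, "pvsh_cc", rep(TRUE, nrow(co)), normalize = FALSE)
backwardsElimination(nz$data, "speed", candidates = "pvsh_cc_z",
                     forced = c("age", "sex", "education"))
#> Backwards elimination for 'speed' (n = 265, alpha = 0.05)
#> Retained:
#>       term   beta partial_r2        p forced
#>        age -0.322      0.105 7.75e-08   TRUE
#>        sex  0.031      0.001 6.00e-01   TRUE
#>  education -0.046      0.002 4.32e-01   TRUE
#>  pvsh_cc_z  0.174      0.033 3.10e-03  FALSE
```

The lesion term is retained at its planted magnitude; the sex and
education covariates, which carry no planted effect, hover near zero.
Pooled-SD effect sizes work directly from group summaries:

```r
cohensDPooled(73.1, 4.6, 265, 79.0, 3.7, 100)
#> Cohen's d (pooled SD): d = -1.349 (|d| = 1.35), pooled SD = 4.373
```

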