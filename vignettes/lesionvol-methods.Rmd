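---
title: "Quantifying subcortical hyperintensities and atrophy: methods and design"
author: "lesionvol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying subcortical hyperintensities and atrophy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionvol)
```

## What the package computes

Subcortical hyperintensities (SH) are bright regions on proton-density (PD)
and T2-weighted MRI of the aging brain, widely read as markers of
small-vessel disease. Quantitative SH studies chain several stages: skull
removal and supratentorial total intracranial volume (ST-TIV), T1-based
tissue segmentation (gray matter, white matter, sulcal and ventricular
CSF), PD/T2-based SH detection split into periventricular (pvSH) and
deep-white (dwSH) compartments by 3D connectivity, extraction of
cystic lacunar cores from T1, parcellation into 26 standardized volumes of
interest (VOIs), and a statistical stage relating regional volumetrics to
cognition: normal-referenced composite z-scores, covariate-adjusted group
contrasts with pooled-SD effect sizes, and backwards-elimination linear
regression under a lobar-then-subregion stepwise strategy.

`lesionvol` implements this chain end to end at desk scale, together with a
synthetic-data stage that makes every link testable against exact ground
truth: analytic multimodal brain phantoms and linear-Gaussian cohorts with
known planted structure.

## The phantom generator

The phantom is deliberately analytic rather than template-based: nested
ellipsoids (a sulcal-CSF shell under the dura, a cortical GM shell, a WM
interior, two mirrored ventricular ellipsoids) whose class volumes are
known exactly, so segmentation accuracy can be asserted rather than
eyeballed.

Lesions are placed by rule:

* **Periventricular lesions** grow outward from a seed voxel on the
  ventricle surface, taking the nearest white-matter voxels until the
  requested volume is met. Growth through WM only guarantees the component
  touches ventricular CSF and never crosses into cortex or sulcal CSF.
* **Deep-white lesions** take the WM voxels nearest a requested centroid,
  constrained to stay at least `dwGapVoxels` (default 3) Chebyshev voxels
  from the ventricular mask, so the connectivity-based pv/dw split has an
  unambiguous correct answer.
* **Lacune cores** relabel the parent lesion's voxels nearest its centroid.

Realized volumes equal `round(volume / voxelVolume)` voxels, hence differ
from the request by at most one voxel volume.

Intensities are class-conditional Gaussians per modality plus one global
additive noise term. The default model puts CSF < GM < WM on T1, makes SH
isointense to WM on T1 (which is exactly why a T1-only segmentation cannot
see it, and why the PD/T2 stage exists), and makes SH and lacune cores
clearly hyperintense to WM on PD and T2, with lacune cores CSF-dark on T1.
Two deliberate simplifications: the per-class intensity SDs default to zero
so that "zero noise" is literally noise-free and exact recovery is a
meaningful assertion, and noise is additive Gaussian — Rician scanner
statistics, bias fields and partial-volume blur are out of scope because
the phantom verifies algorithms, not scanner realism. On PD the default
gives WM a slightly higher mean than GM (real PD contrast is the reverse);
with GM above WM, any single-modality threshold keyed to WM statistics
would sweep up cortex wholesale, and the phantom would no longer separate
"joint-threshold logic works" from "cortical exclusion works".

Noise conditions quoted as a *fraction of the inter-class gap* refer to
`interClassGap()`: the minimum of the contrasts the pipeline must actually
resolve (T1 CSF–GM, T1 GM–WM, PD WM–SH, T2 WM–SH), 30 intensity units for
the default model. All randomness is driven by one integer seed through
named streams, so the phantom, the cohort generator and every pipeline
stage are independently reproducible.

The default phantom is a 72 × 88 × 64 grid at 2 mm isotropic voxels
(~1.13 L brain, in the adult supratentorial range), with 6 cc of
periventricular lesion load, a 0.6 cc deep lesion and a 0.05 cc lacune —
volumes in the range reported for dementia-clinic cohorts. This size keeps
a full segmentation run in the seconds range, which is what makes the
multi-seed recovery studies in the test suite practical.

## Brain extraction and ST-TIV

Extraction is threshold-plus-morphology: a head/background threshold, the
largest 26-connected component, binary closing, and hole filling so the
mask includes all interior CSF (ST-TIV is parenchyma + SH + lacunes +
sulcal and ventricular CSF under the dura). The threshold comes from a
four-component Gaussian mixture of the whole-scene histogram, cutting
midway between the background component and the lowest in-head component.
A two-class histogram split (Otsu) is the textbook choice but fails on
scenes like ours where the dominant separation is CSF-versus-parenchyma
rather than air-versus-head; the mixture cut is equally deterministic and
lands between air and CSF by construction. Interactive edge completion and
cerebellum removal from the clinical workflow are represented by an
optional exclusion mask, a no-op on phantoms, which have no subtentorial
compartment.

## Tissue segmentation: localized four-Gaussian fitting

T1 intensities inside the mask are fitted with a four-component Gaussian
mixture, globally and then within overlapping cubic windows (32³ voxels,
stride 16, i.e. 50% overlap — the window scale adapts to slow intensity
drift while keeping ≥500 in-mask voxels per fit; smaller windows inherit
the global fit). EM is deterministic: quantile-based initialization
(evenly re-spread when degenerate), log-space responsibilities, SDs floored
at 0.1% of the intensity range, components with vanishing weight pruned,
convergence at relative log-likelihood 1e-6 or 200 iterations. Fits use a
deterministic stride subsample of up to 8000 voxels per window;
classification always uses every voxel.

Two design points deserve justification:

* **Component semantics.** With four well-separated components the global
  model reads, in ascending T1 mean, CSF / CSF–GM partial-volume shoulder /
  GM / WM; the partial component's mass is reassigned per voxel to CSF or
  GM by posterior odds, so the emitted classes are always the three
  tissues. When the scene genuinely contains fewer intensity populations
  (a noise-free phantom has exactly three), duplicated components fitted to
  one population are merged before class assignment — otherwise an
  ascending-rank rule would split one tissue across two labels.
* **Window-to-class matching.** Window components are matched to global
  classes by nearest global mean, not by within-window rank. A window deep
  in white matter may contain only one or two populations; rank-based
  assignment would label them CSF upward, which is catastrophic, while
  nearest-mean matching is exact in that case.

Per-voxel class posteriors from all covering windows are blended with
trilinear tent weights centered on each window and renormalized; the label
is the maximum-posterior class. Ventricular CSF is then separated from
sulcal CSF by 26-connected flood fill from supplied seed voxels (ground
truth provides them on phantoms; fully automatic ventricle detection is out
of scope). Bias-field correction and multispectral tissue classification
are likewise out of scope.

## SH detection, pv/dw split, lacunes

A voxel is an SH candidate iff it lies in the mask and its PD **and** T2
intensities both exceed the WM mean by `zThreshold` (default 3) SDs, with
WM statistics estimated from WM-labeled voxels per modality. The joint
requirement is what suppresses single-modality excursions — including the
phantom's cortical GM, which is PD-bright but T1/T2-typical. Ventricular
CSF and surface-connected sulcal CSF are excluded, with one carve-out:
voxels that are CSF-dark on T1 *and* pass both hyperintensity thresholds
show precisely the lacune signature and keep their candidacy (a
periventricular lacune core contiguous with the ventricle would otherwise
be flood-filled into vCSF and become undetectable, contradicting the
operational lacune definition). Candidates whose 26-neighborhood holds a
majority of non-candidate GM voxels are dropped (cortical false-positive
control), and components under `minComponentVoxels` (default 5) are
removed as speckle.

Components are labeled at configurable connectivity (default 26) and
classified **periventricular** iff any voxel lies within
`pvDistanceVoxels` (default 1, Chebyshev) of ventricular CSF, else **deep
white** — a connectivity rule, not a fixed-millimeter or proportional
distance. The test suite holds this equivalent to an independent
dilate-and-intersect oracle. Finally, SH voxels below the CSF T1 mean plus
two CSF SDs are relabeled lacune, each lacune component keeping a link to
its parent SH component; reassignment conserves total SH volume by
construction. FLAIR-based detection and perivascular-space modeling are
non-goals.

## Parcellation and volumetrics

The published landmark-based 26-region protocol is replaced by a
deterministic plane-based analog exposing the same interface: a sagittal
midline, coronal cuts at configurable fractions of the anterior–posterior
extent (defaults 0.40/0.75), an axial temporal carve-out, and
medial/lateral and axial subdivisions yielding 13 regions per hemisphere —
including the medial middle frontal and anterior/posterior temporal
regions the statistical stage needs. Anatomical fidelity is a non-goal;
partition exactness is asserted (regions are disjoint, their union is the
mask, left/right mirror on a symmetric mask). Voxels are counted where
they lie, so regional volumes are additive to whole-brain volumes exactly.

Profiles report raw cc per class per VOI, ST-TIV, brain parenchymal
fraction `BPF = 100·(GM+WM)/ST-TIV` and the ventricular atrophy ratio
vCSF/ST-TIV. Head-size normalization divides by ST-TIV (matching the
vCSF/ST-TIV convention; a residual-regression alternative was considered
and rejected as needlessly model-dependent here). A variable whose
reference-sample skewness (adjusted Fisher–Pearson) exceeds 1.0 is
log-transformed with offset equal to the smallest positive observed value —
chosen so the many genuinely zero lacune loads stay in the sample — before
z-scoring against the reference (normal-control) mean and SD. The
reference defaults to controls only, matching the composite-score
convention; zero-variance variables are flagged rather than fatal.

## The statistical stage

* **Composites.** Each test is z-scored against the control sample and
  sign-flipped where a higher raw score is worse (completion times, error
  counts), so every domain composite reads higher = better; a subject needs
  at least one test per domain. The executive domain pools verbal fluency
  and three card-sorting scores; speed is the Trail-Making-A time; memory
  pools verbal learning, visual reproduction and a rating-scale memory
  subscore.
* **Effect sizes.** Cohen's d by the pooled-SD formula
  `sqrt(((n1-1)s1² + (n2-1)s2²)/(n1+n2-2))`; tables report |d|.
* **ANCOVA.** OLS of the outcome on a group indicator plus covariates
  (age, sex, education by default), reporting the adjusted group
  coefficient; rank deficiency raises a collinearity error naming the
  aliased columns.
* **Backwards elimination.** Outcome and predictors are z-scored (so
  coefficients are standardized β), the model is refitted repeatedly, and
  the highest-p candidate above α = 0.05 is removed, ties broken by
  smaller |β|; forced covariates are never dropped by default (a flag makes
  them eligible, since published models sometimes omit them). Per-predictor
  R² is the squared partial correlation t²/(t²+df) — printed tables rarely
  define their R², and this choice is recorded in the output. α is
  configurable (0.10 documented as an alternative; published tables
  sometimes keep a p = 0.06 term).
* **Stepwise VOI strategy.** Stage 1 runs elimination on the four lobar
  aggregates (sums of subregion z-scores) plus covariates; each lobe
  retained at p ≤ α gets a stage-2 elimination over its ≤ 6 subregions. No
  multiplicity correction is applied by default, matching standard practice
  for this design; `p.adjust`-style correction can be applied downstream.
* **Partial regression.** Residual-on-residual series whose slope equals
  the joint-model coefficient (Frisch–Waugh), asserted to 1e-10.

## The cohort generator

Synthetic cohorts draw base variables per group (Gaussian; Bernoulli for
binary; log-normal matched on median and IQR for the right-skewed lesion
loads) and then build outcomes as `Σ β·z(predictor) + ε` with predictors
z-scored on their group's specified scale, so planted β are standardized
effect sizes and recovery can be tested without rescaling. The default
spec mirrors a dementia-clinic case-control sample (AD n = 265, NC
n = 100; AD older, less educated, MMSE 23.2 vs 29.0, BPF 73.1% vs 79.0%,
skewed SH loads). For the stepwise recovery study, subregion lesion
z-scores within a lobe share a common factor (correlation 0.5) — within-lobe
lesion burden is correlated in real cohorts, and a lobar-aggregate screen
is only a sensible design under that assumption. MMSE is clamped to
[0, 30] after noise.

What passing these simulations does *not* show: robustness to scanner
artifacts, registration error, non-Gaussian residuals, or confounded
covariates — the generators are linear-Gaussian by design, so the tests
verify the estimators and the pipeline plumbing, not clinical validity.

## Numerical and degenerate-input policy

Empty scenes, empty masks, zero ST-TIV, seeds outside CSF, undefined
generative predictors, >6 VOIs per model, and aliased design columns are
errors with named culprits. An empty SH mask is a valid empty result, not
an error. EM degeneracies (SD collapse, vanishing weight) are handled by
flooring, pruning and merging as described, with global-model fallback for
under-populated windows. Elimination ties break on smaller |β|;
`max.col` ties in classification break on the first class; both are
deterministic. Problem sizes used by the shipped studies (phantom grids,
5 seeds per noise level, 200-rep recovery studies, 1000-rep calibration)
were chosen as the smallest sizes at which the Monte-Carlo error is
comfortably below the margins being asserted.

## Known limitations

Phantom anatomy is convex-ellipsoidal; there is no gyrification, no
partial-volume blur, no bias field, no registration stage. The parcellation
is geometric, not anatomical. Ventricle seeds must be supplied on real
data. PD/T2 are assumed co-registered with T1 at equal resolution. The
statistical stage fits cross-sectional linear models only — no mixed
effects, no longitudinal change metrics.
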