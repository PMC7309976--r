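---
title: "Building and evaluating CT radiomics signatures with radsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and evaluating CT radiomics signatures with radsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Triple-negative breast cancer (TNBC; ER-, PR-, HER2-) is the breast-cancer
subtype with the fewest targeted treatment options, and knowing the subtype
before surgery changes how a patient is managed. Molecular subtyping needs
tissue; contrast-enhanced chest CT is often already available. Radiomics
asks whether the tumor's CT appearance — its intensity statistics, shape,
and spatial texture — carries enough signal to predict the subtype
non-invasively.

`radsig` implements that analysis end to end: 3D radiomic feature
extraction from a delineated tumor volume of interest (VOI), feature
selection by SVM-based recursive feature elimination and LASSO-penalized
logistic regression on a discovery cohort, a linear *radiomics score*, and
diagnostic evaluation (ROC/AUC with DeLong intervals, Youden cutoff,
sensitivity/specificity/PPV/NPV with Clopper-Pearson intervals,
inter-observer ICC, and baseline group comparisons). Because no imaging
cohort of this kind is publicly deposited, the package also ships a
synthetic CT cohort generator that plants controllable class differences,
so every stage can be exercised and tested at desk scale.

## The model

For patient $i$ with feature vector $x_i$ the signature is a sparse linear
score

$$\mathrm{score}_i = \beta_0 + \sum_{j \in S} \beta_j \, z_{ij},$$

where $z_{ij}$ are z-scored features (parameters learned on the discovery
split only) and the support $S$ comes from L1-penalized logistic
regression: $\hat\beta = \arg\min_\beta \; \ell_{\mathrm{binomial}}(\beta)
+ \lambda \lVert \beta \rVert_1$, with $\lambda$ chosen at the minimum
mean cross-validated binomial deviance over a stratified 10-fold split
(`lambda_rule = "min"`; the sparser one-standard-error rule is available).
TNBC is coded 1, so larger scores mean "more TNBC-like". A reference
five-feature published model (intercept $-2.21$; coefficients $+0.03$
compactness, $-55.21$ GLZM, $+0.18$ GLSZM, $+0.36$ band-max, $+1.69$
band-mean) is bundled as `published_signature()` and is evaluated only on
feature maps that provide exactly those names — its feature labels are not
resolvable to catalogue entries, so it is treated as an external model,
not re-derived.

```{r}
library(radsig)
spec <- cohort_spec(seed = 1)            # 100 TNBC / 200 NTNBC, 180/120
ft <- simulate_cohort_features(spec)     # in-memory cohort + 182 features
ids <- feature_catalogue()$id
disc <- ft$split == "discovery"
y <- as.integer(ft$label == "TNBC")
fit <- radiomic_signature(ft[disc, ids], y[disc], seed = 7)
summary(fit)
val_scores <- predict(fit, ft[!disc, ids])
diagnostic_report(val_scores, y[!disc],
                  cutoff = optimal_cutoff(predict(fit, ft[disc, ids]),
                                          y[disc]),
                  cohort = "validation")
```

## The feature catalogue

The catalogue is fixed, ordered, and versioned: 18 first-order + 12 shape
+ 2 discretizations $\times$ (25 GLCM + 16 GLRLM + 16 GLSZM + 5 NGTDM +
14 GLDM) = **182 features**. Only the total and the family names are
constrained by the analysis the package reproduces; the concrete layout is
this package's choice and is declared in `feature_catalogue()` /
`write_catalogue()` so the count is testable. Both a neighbourhood
grey-tone difference matrix (NGTDM) and a grey-level dependence matrix
(GLDM) family are included because the acronym "GLDM" is used for both in
the literature.

Preprocessing before texture computation:

* **Resampling** — images trilinear, masks nearest-neighbour, to an
  isotropic grid; default 1 mm (matching thin-slice CT), configurable, and
  skipped when the data are already on the target grid.
* **Discretization** — fixed bin count, `level = min(G, floor(G (x -
  min)/(max - min)) + 1)`; the catalogue computes texture at G = 32 and
  G = 64. A constant VOI maps to level 1 (avoids 0/0). A fixed bin-width
  rule is also available.
* **Resegmentation** — an optional intensity window dropping foreground
  voxels outside `(lo, hi)`, the automatable surrogate for the manual
  exclusion of necrosis/calcification/gas; off by default.

Degenerate-VOI conventions (all tested): constant VOI has entropy 0,
uniformity 1, GLCM correlation 1, skewness/kurtosis 0 (population moments,
non-excess kurtosis: a Gaussian scores 3); NGTDM coarseness is capped at
$10^6$; a single-voxel VOI has zero diameter and elongation 1.

Texture aggregation uses the 13 unique 3D directions at distance 1:
per-direction GLCMs are normalized then averaged; GLRLM run counts are
merged across directions before the feature formulas. Both choices are the
most common conventions and are stated here because they change third
decimals.

Three geometric quantities are computed by purpose-built code because no
installed package provides them in 3D:

* **Mesh surface area** — marching tetrahedra with linear interpolation
  over a lightly anti-aliased (Gaussian, $\sigma = 0.7$ voxel) copy of the
  mask. Interpolating on the smoothed field removes the voxel staircase:
  a digital ball of radius 10 voxels is measured within about 1% of
  $4\pi r^2$ (binary midpoint meshes overestimate by ~28%). Masks too
  small to survive smoothing fall back to the binary mesh.
* **Concavity** — $1 - V/V_{\mathrm{hull}}$ with the convex hull of the
  boundary-voxel centres *rasterized back onto the voxel grid* (voxel
  centres inside the hull are counted). Comparing voxelized solid with
  voxelized hull makes digitization cancel in the ratio: convex digital
  solids score ~0, an L-shaped prism scores ~0.3. The hull itself is an
  incremental 3D hull; grid degeneracy is broken by a deterministic
  sub-voxel jitter (amplitude 0.02 voxel, fixed internal seed), far below
  any geometric tolerance.
* **Largest-slice perimeter** — marching squares on the largest-area
  axial slice (the only self-consistent reading of a 2D "perimeter" for a
  3D lesion).

## The synthetic cohort generator

`cohort_spec()` defaults define the study conditions: 100 TNBC / 200
NTNBC, stratified 60% discovery split (`round(0.6 n)` per class, giving
exactly 180/120), one lesion per patient on a 30^3 grid at 1 mm spacing
with effective radius 4-8 mm. Each lesion is an ellipsoid whose boundary
is deformed by a smooth low-order radial perturbation (class-specific
amplitude) and whose interior is Gaussian-correlated noise — white noise
smoothed with a kernel equal to the class correlation length, rescaled to
the class intensity SD — plus a low-frequency sinusoidal intensity band.
The second "observer" mask is a random one-step dilation or erosion of the
primary mask. The lesion-scale and intensity defaults are free parameters
chosen as plausible for contrast-enhanced breast lesions on CT (soft-tissue
background ~40 HU, lesions 60-70 HU), not estimates of any real
population: no lesion-size or intensity statistics are available for a
cohort of this kind.

Per-patient substream seeds are drawn once from the master seed, so a
cohort is bit-reproducible and any single patient can be regenerated.
Class differences enter only through the texture/shape parameters: with
identical per-class parameters the downstream AUC is indistinguishable
from 0.5 (tested), and with the default class-divergent parameters the
planted effect is strong (validation AUC far above chance). What passing
these tests shows is that the pipeline transmits a known texture contrast
into classification performance without leakage — not that real TNBC is
this easy; real CT has scanner effects, anatomy, and far subtler class
differences that the phantom does not emulate.

## Selection and evaluation choices

* **Stage order** — variance filter (raw scale, threshold 0 = drop
  constants) -> z-score (discovery-learned) -> SVM-RFE -> LASSO. Method
  descriptions in this literature sometimes list SVM-RFE ahead of
  variance filtering, which is not operational (RFE needs non-constant,
  scaled input); the order used here makes every stage's preconditions
  satisfiable, and each stage is configurable.
* **SVM-RFE** — an RBF kernel (C = 0.78, gamma = 0.00069, as published)
  has no native coefficient vector, so per-feature importance within each
  round is permutation importance: the drop in 5-fold cross-validated
  accuracy when that feature is permuted in the held-out fold. Each round
  eliminates the bottom 10% until `rfe_k` (default 30) remain. Seeded and
  deterministic.
* **ROC** — AUC by the rank (Mann-Whitney) identity with midranks;
  DeLong 95% CI. Cutoff maximizes Youden's J over observed scores with
  ties broken toward higher specificity; `score >= cutoff` calls TNBC.
  The validation split is always scored with discovery-learned
  normalization, model, and cutoff.
* **Proportion CIs** — exact Clopper-Pearson, the standard exact choice
  when no interval method is otherwise prescribed; coverage is verified
  by simulation in the test suite.
* **ICC** — two-way ANOVA decomposition; default ICC(2,1)
  (random-effects, absolute agreement — the clinically relevant question
  for two radiologists), ICC(3,1) available; F-based 95% CIs; reliability
  flag at ICC > 0.75. Written in-package because no ICC implementation is
  available in the supported dependency set.
* **Group comparisons** — Pearson chi-square without continuity
  correction, Welch t, or Mann-Whitney (exact for small untied samples,
  normal approximation with tie correction otherwise), matching standard
  baseline-table practice.

## Numerical and testing notes

Coordinate convention: voxel indices are 0-based internally; world
coordinates follow the NIfTI affine; masks are interpreted on the image
grid (no registration). Geometry tolerance for mask/image agreement is
1e-3 mm. The LASSO uses coordinate-descent tolerance 1e-7.

Problem sizes used by the test suite are deliberate choices: oracle
equivalence runs on VOIs of at most 64 voxels against naive enumeration;
the rank identity uses 100 random datasets; ICC recovery uses 200
subjects; LASSO support recovery uses n = 200, p = 30 over 20 seeds; the
end-to-end experiment runs the full 300-patient cohort for 10 planted and
6 null seeds with the RFE stage disabled (the RFE stage has its own
planted-signal test; disabling it keeps the experiment focused on the
signature fit). The support-recovery Jaccard check uses the
one-standard-error lambda rule because minimum-deviance LASSO
intentionally over-selects.

## Limitations

No DICOM ingestion, registration, or automatic segmentation; no filtered
(wavelet/LoG) feature families; no probability calibration; the published
five-feature model can only be applied to tables that already provide its
named inputs. The synthetic phantom does not emulate scanner or
acquisition effects, and its defaults are not population estimates.
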