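---
title: "Quantifying inter-tumor heterogeneity on multi-lesion PET/CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying inter-tumor heterogeneity on multi-lesion PET/CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

High-grade serous ovarian cancer typically presents with a primary adnexal
mass plus multiple peritoneal implants. Lesion-to-lesion (*inter-tumor*)
heterogeneity — how different a patient's lesions are from one another —
carries prognostic information that per-lesion (*intra-tumor*) radiomics
ignores. `ithet` quantifies that heterogeneity from co-registered PET/CT
volumes and delineated lesion masks, and feeds it into penalised Cox models
of progression-free (PFS) and overall survival (OS).

The pipeline has four stages:

1. **Per-lesion conventional measurements.** Every retained volume of
   interest (VOI) yields eight measurements: voxel count (`Pixel_number`),
   major/minor axis length in mm (`Maj`, `Min`), mean attenuation (`HU`),
   `SUVmax`, `SUVmean`, `SUVpeak` and total lesion glycolysis (`TLG`).
2. **Cross-lesion statistics.** Each measurement is summarised across the
   patient's lesions with 13 statistics (mean, median, mode, quartile
   deviation `R`, SD, SE of the mean `SM`, variance, range, CV, corrected and
   uncorrected sums of squares, kurtosis, skewness), giving
   8 x 13 = 104 conventional heterogeneity metrics named
   `<Measurement>_<Statistic>`.
3. **CT-texture heterogeneity.** Three metrics — cluster site entropy
   (`cSE`), cluster standard deviation (`cluDev`) and cluster dissimilarity
   (`cluDiss`) — summarise how dissimilar the lesions' CT textures are,
   via GLCM/Haralick features, voxel subregion clustering and the grey level
   distance zone matrix (GLDZM). The full patient-level vector has
   107 entries.
4. **Prognostic modelling and validation.** LASSO-Cox models on three
   feature sets (conventional, heterogeneity, integrated), evaluated by
   Harrell's C, Kaplan–Meier/log-rank stratification and IPCW
   time-dependent ROC; risk scores are correlated with p53/Ki-67
   immunohistochemistry H-scores, and metric reproducibility is screened by
   test-retest ICC.

Because no suitable public multi-lesion PET/CT cohort exists, the package
ships a synthetic phantom-cohort generator with planted ground truth, so the
entire pipeline is testable end to end.

## VOI rules and conventional measurements

A lesion enters the analysis only if its mask bounding box exceeds
5 mm in every dimension, and only the largest lesion (by voxel count) per
anatomical region is kept; regions follow a 9-zone abdominopelvic code
(`AR-0` … `AR-8`) plus `primary`. Patients contribute one primary lesion and
1–9 implants; inter-tumor metrics require at least two lesions.

Numerical conventions, chosen where the field leaves latitude and fixed
here:

* **Axis lengths** come from the eigen-decomposition of the masked voxel
  point cloud's coordinate covariance (physical mm), with axis length
  `4 * sqrt(eigenvalue)` — the image-moment convention used by the common
  radiomics toolkits. For a solid ball of diameter *d* this yields
  `2 d / sqrt(5) = 0.894 d` exactly; the tests assert against that closed
  form, not against *d*.
* **SUVpeak** is the maximum over masked voxels of the mean SUV in a
  1 cm^3 sphere (radius 6.2 mm) centred on the voxel, with the sphere
  clipped to the mask — the EANM-style definition.
* **TLG** is `SUVmean x volume(mL)` over the whole mask; no percentage
  threshold sub-volume is applied.
* **HU** is the arithmetic mean attenuation over the mask.

## The 13 cross-lesion statistics

With so few values per patient (2–10 lesions), small-sample conventions
matter and are fixed as follows: variance, SD and `SM` use the sample
(n−1) divisor; skewness and excess kurtosis use population central moments
so they are defined from n = 2, and are set to 0 when the second moment
vanishes; the mode of continuous values rounds to 4 significant digits,
takes the most frequent value and breaks ties toward the smallest; `R` is
the semi-interquartile range `(Q3 − Q1)/2` with linear-interpolation
quantiles; `CV` divides by `|mean|` (0 for a zero mean) and is not
multiplied by 100. The identity `USS = CSS + n * mean^2` and scale
covariance of each statistic are enforced by property tests against an
independent brute-force implementation.

## CT-texture heterogeneity metrics

Texture uses CT only; PET contributes through the conventional block.

1. **Discretization.** Masked HU values are rescaled linearly to integers
   0–255 over the lesion's own min–max range, then binned with width 32,
   giving G = 8 gray levels. Per-lesion rescaling makes the texture metrics
   invariant to constant attenuation shifts; a fixed-window alternative was
   considered and rejected because scanner-level calibration offsets would
   otherwise masquerade as heterogeneity.
2. **GLCM / Haralick.** Co-occurrences are counted over the 13 unique 3-D
   offsets at distance 1 voxel, both voxels in-mask, symmetrised, merged
   over offsets and normalised — the "merged" aggregation of the IBSI
   framework. Energy, entropy (bits), contrast and homogeneity are computed
   per lesion and logged as intermediates.
3. **Subregions.** Each masked voxel is described by (gray level,
   3x3x3 local mean, 3x3x3 local SD; neighbourhoods clipped to the mask),
   standardised per lesion and partitioned by k-means with k = 3 and
   10 restarts. One shared RNG substream seeds the clustering of every
   lesion, so identical lesions produce identical subregions and the
   patient-level metrics are invariant under lesion reordering. Constant
   lesions collapse to a single subregion.
4. **cSE.** All subregion centroids of the patient are pooled; their
   pairwise Euclidean distances are binned into 10 equal-width bins over
   [0, max]; `cSE` is the Shannon entropy (bits) of the bin frequencies,
   and 0 when all centroids coincide.
5. **GLDZM, cluDev, cluDiss.** Zones are 26-connected components of equal
   gray level; each zone is indexed by its minimum Chebyshev distance to the
   mask border (border voxel = 1). Distances are collapsed into 4 relative
   bands (quartiles of the lesion's maximum border distance) so the G x 4
   matrix is comparable across lesion sizes, and normalised by the zone
   count. `cluDiss` is the mean, and `cluDev` the population SD, of the
   upper-triangle Euclidean distances between the lesions' flattened GLDZM
   vectors.

The reading that `cSE` derives from the pooled subregion dissimilarities
while `cluDev`/`cluDiss` derive from the inter-lesion GLDZM dissimilarity
matrix is the only one that yields exactly three texture metrics from the
six processing steps; it is a documented surrogate for a procedure whose
full details live outside the main-text description this package follows,
and any refinement can be substituted behind the same function contracts.

## Prognostic models

`assemble_feature_table()` builds one of three design matrices —
conventional (clinical covariates + primary-lesion measurements, 32
columns), heterogeneity (the 107 metrics), integrated (their union) —
standardised to training-set mean 0 / SD 1; test rows always reuse training
constants, and zero-variance training columns are dropped and logged.
CA125 and ascites volume are used untransformed by default (log1p switches
are provided).

`fit_ith_cox()` is the modelling core: an L1-penalised Cox partial
likelihood over glmnet's log-spaced penalty grid, with λ chosen by the
CV-optimal (λ-min) rule under event-stratified fivefold cross-validation.
λ-min rather than λ-1se is deliberate: with 100+ correlated candidate
metrics the 1se rule collapses to near-empty models, while the desired
behaviour is a richer selected set. Ties are handled by Breslow throughout,
no interactions are included, and the returned `ith_cox` object carries the
selected coefficients, the CV trace, the Breslow baseline cumulative hazard
and the training risk-score median (the Kaplan–Meier split point reused on
test data). `print`, `summary`, `coef`, `predict`, `plot`, `residuals`
(martingale) and `simulate` (baseline-hazard inversion) methods are
provided.

Evaluation: Harrell's C counts a pair as usable when the shorter observed
time is an event, scores ties as 1/2, and gets its 95% CI from a seeded
1000-replicate bootstrap percentile interval (the CI method is a package
choice; it is not prescribed by the reporting contract it serves).
Time-dependent AUC is the cumulative/dynamic IPCW estimator with
Kaplan–Meier censoring weights, evaluated at 1–3 years for PFS and
1–5 years for OS by default. Hazard ratios for a risk score come from
unpenalised `coxph` fits, univariate or adjusted for the clinical
covariates.

## Agreement and correlation

The H-score is `%weak x 1 + %moderate x 2 + %strong x 3` (range 0–300).
Spearman correlations between model risk scores and H-scores use average
ranks for ties; the p-value uses the exact permutation null up to n = 8
(40 320 permutations) and the t-approximation above — full enumeration at
n = 9–10 would cost six orders of magnitude more for no practical gain at
the cohort sizes involved. Correlation runs on the subset of patients with
stain data; no imputation.

ICC forms: intra-session reproducibility uses ICC(3,1) (two-way mixed,
consistency); inter-observer uses ICC(2,1) (two-way random, absolute
agreement); both from the standard mean-square decomposition and validated
against `aov()`-based arithmetic. The reproducibility screen computes a
per-metric ICC between two extraction runs and flags metrics above a 0.75
threshold.

## The synthetic cohort: what it does and does not emulate

`simulate_cohort()` generates patients as follows, with defaults fixed once
to mirror the emulated study conditions:

* **Geometry.** Voxel spacing (1, 1, 3.8) mm (about 1 mm in-plane CT with
  3.8 mm slices); lesions are ellipsoids of diameter 12–30 mm; 1–9 implants
  (median ≈ 6) placed in distinct regions with the documented region
  frequencies (pelvis most often involved).
* **Intensities.** Within-lesion texture is Gaussian-correlated noise
  (correlation scale 2.5 mm, HU noise SD 10), centred and scaled over the
  mask so the lesion's noise statistics match the request exactly. Each
  lesion additionally carries a concentric core (relative radius 0.3–0.6)
  with a CT offset, emulating the hypo-/hyperdense cores of partly necrotic
  or fibrotic implants; between-lesion spread of all intensity/texture
  parameters scales with a single dispersion dial (a per-patient lognormal
  latent times `lesion_dispersion`). The core component is what gives the
  zone-matrix metrics something real to detect: min–max discretization
  deliberately removes pure mean/SD differences.
* **Covariates.** Age, CA125, FIGO stage, resection status, ascites,
  nodal/implant flags, invasion pattern and solid ratio are drawn from the
  category frequencies of an advanced-stage serous cohort (e.g. FIGO IIIC
  ≈ 57%, R0 ≈ 57%).
* **Survival.** Event times are exponential with rate
  `baseline_rate x exp(lp)`; baselines give median PFS ≈ 645 days and
  median OS ≈ 1022 days at the cohort-median linear predictor. The planted
  linear predictor combines clinical effects (FIGO, R2 resection,
  log CA125), effects on ground-truth conventional heterogeneity metrics
  (computed from the noiseless lesion parameters and standardised
  cohort-wise), and a latent-dispersion effect that drives the texture
  metrics. Censoring is the minimum of uniform dropout on [0, 3300] days
  and an administrative horizon of 2500 days (~30% censoring for PFS);
  the censoring mechanism is a stated default, not an inference.
* **H-scores.** A Gaussian copula on the risk ranks (Pearson
  `2 sin(pi rho / 6)` so the Spearman correlation converges to the 0.85
  target) is mapped to an H-score in [0, 300] and decomposed
  deterministically into a weak/moderate/strong triple summing to at most
  100%.
* **Reproducibility.** `perturb_segmentation()` emulates a repeat
  delineation: a smooth random field pushes or pulls one boundary voxel
  layer per step up to the requested physical magnitude, moving only along
  axes whose spacing does not exceed it (a 1 mm perturbation is in-plane
  only), never emptying the mask.

What the phantoms do **not** emulate: irregular lesion shapes, anatomical
context, scanner physics (partial volume, reconstruction artefacts),
attenuation cross-talk between PET and CT, or correlated delineation bias
between observers. Passing tests therefore certify the *computational*
pipeline — definitions, invariances, recovery of planted signal — not
clinical performance on real images.

## Determinism and problem sizes

Every generator and every stochastic fit is a pure function of its
configuration and an integer seed; a single master seed is expanded into
counter-based substreams per patient, lesion and pipeline stage, so results
are independent of generation order. The validation suite exercises the
pipeline at deliberately chosen sizes: brute-force oracle comparisons on
small random instances; planted LASSO-Cox selection at n = 300 over
20 seeds; Cox coefficient recovery at n = 500; the image-level
planted-signal harness at 300 patients with 8–14 mm lesions; the model
ranking check at 150 patients; and the test-retest ICC screen on a
30-patient cohort at the default lesion sizes, where ≥ 95% of the 107
metrics exceed ICC 0.75 after a 1 mm simulated re-segmentation. Metrics
that sit below the threshold there are instructive: the mode of a handful
of continuous values is intrinsically discontinuous under perturbation, and
the GLDZM border-distance bands shift when the border itself moves.

## Known limitations

* The texture-metric construction (clustering feature space, k, similarity
  binning, GLDZM banding) is a documented reference procedure; other
  reasonable choices exist and would change absolute metric values, though
  not the invariances tested here.
* The 4-significant-digit mode convention makes `*_Mode` metrics the least
  reproducible of the 13 statistics under segmentation noise.
* Harrell's C at O(n^2) pairs and the exhaustive Spearman permutation null
  are intended for cohort-scale n, not biobank-scale data.
* With two lesions, `cluDev` is exactly 0 and skewness/kurtosis are
  degenerate (0); models should treat those columns accordingly (zero
  variance columns are dropped at assembly).
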