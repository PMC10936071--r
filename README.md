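# ithet — inter-tumor heterogeneity metrics and prognostic models for multi-lesion PET/CT

Patients with advanced high-grade serous ovarian cancer usually carry one
primary tumor plus several peritoneal implants. How *different* those
lesions are from one another — lesion-to-lesion, or inter-tumor,
heterogeneity — is prognostic information that single-lesion radiomics
cannot see. `ithet` turns co-registered PET/CT volumes with delineated
lesion masks into a 107-entry patient-level heterogeneity vector and fits
penalised survival models on it:

* **8 conventional measurements per lesion** — voxel count, major/minor
  axis length (mm), mean attenuation (HU), SUVmax, SUVmean, SUVpeak
  (1 cm³-sphere peak), total lesion glycolysis (TLG = SUVmean × volume);
* **13 cross-lesion statistics per measurement** — mean, median, mode,
  quartile deviation R, Std_dev, SM (standard error of the mean), variance,
  range, CV, CSS, USS, kurtosis, skewness — giving 8 × 13 = **104
  conventional metrics** named `<Measurement>_<Statistic>`
  (e.g. `SUVmean_CV`);
* **3 CT-texture metrics** — cluster site entropy (**cSE**), cluster
  standard deviation (**cluDev**) and cluster dissimilarity (**cluDiss**) —
  from 8-level min–max discretization, 3-D GLCM/Haralick features, voxel
  subregion clustering, and grey level distance zone matrices (GLDZM)
  compared between lesions by Euclidean distance.

Downstream, `fit_ith_cox()` fits a LASSO-Cox model (event-stratified
fivefold cross-validation, λ-min rule) on one of three feature sets —
conventional, heterogeneity, or integrated — and the package evaluates it
with Harrell's C (bootstrap CI), Kaplan–Meier/log-rank risk stratification,
IPCW time-dependent ROC, and unpenalised Cox hazard ratios. Risk scores can
be correlated (Spearman) with p53/Ki-67 immunohistochemistry H-scores, and
metric reproducibility is screened by test-retest ICC.

Because no public multi-lesion PET/CT cohort exists, the package includes a
first-class synthetic cohort generator (`simulate_cohort()`): ellipsoidal
lesion phantoms with correlated noise texture and attenuation cores, 9-zone
abdominopelvic implant placement, realistic clinical covariates,
exponential-baseline Cox survival driven by a planted linear predictor, and
copula-simulated H-scores. Every stage of the pipeline is validated against
brute-force oracles and planted ground truth.

## Worked example

```r
library(ithet)

cfg    <- sim_config(n_train = 60, n_test = 30, lesion_diameter = c(8, 14))
cohort <- simulate_cohort(cfg, seed = 11)
cohort
#> Synthetic multi-lesion cohort: 90 patients (60 train / 30 test)
#> Lesions per patient: median 7 (range 4-10)

het <- heterogeneity_table(cohort, seed = 11)   # 107 metrics per patient
round(unlist(het[1, c("SUVmean_Mean", "SUVmean_CV", "HU_SM",
                      "cSE", "cluDev", "cluDiss")]), 3)
#> SUVmean_Mean   SUVmean_CV        HU_SM          cSE       cluDev      cluDiss
#>        5.181        0.157        2.453        3.129        0.139        0.290

features <- assemble_feature_table(cohort, "heterogeneity", heterogeneity = het)
outcomes <- cohort_outcomes(cohort, "PFS")
fit <- fit_ith_cox(features, outcomes, endpoint = "PFS", seed = 1)
summary(fit)
#> LASSO-Cox model, endpoint PFS, feature set 'heterogeneity'
#> Penalty lambda (CV-optimal over 5 folds): 0.16753
#> Selected 6 features (standardised scale):
#>      SUVpeak_CV         cluDiss       SUVmax_CV SUVpeak_Std_dev      SUVpeak_SM
#>          0.7629          0.3168          0.2310          0.1863          0.0955
#>          cluDev
#>          0.0269
#> Training risk-score median (KM split): -0.3576
```

This cohort was simulated with hazard planted on `SUVmean_CV` (between-
lesion SUV dispersion), on clinical stage/resection covariates, and on the
latent between-lesion texture dispersion — and the model indeed selects the
SUV dispersion family (`SUVpeak_CV`, `SUVmax_CV`, …) together with
`cluDiss`/`cluDev`. Evaluation on the held-out test split:

```r
test   <- cohort$split == "test"
scores <- predict(fit, features)

concordance_index(scores[test], outcomes$time[test], outcomes$event[test], seed = 1)
#> Test-set C-index: 0.834 (95% CI 0.723-0.921)

km_logrank(scores[test], outcomes$time[test], outcomes$event[test],
           threshold = fit$risk_median)
#> Log-rank chi-square = 11.42, p = 0.00073

cox_hr(scores[test], outcomes$time[test], outcomes$event[test])
#> Univariate HR per unit risk score: 3.777 (2.047-6.970)
```

Higher risk scores mean shorter expected survival: the test-set C-index of
0.834 says the model correctly orders ~83% of usable patient pairs, and the
median-split groups differ clearly (log-rank p < 0.001). Correlating risk
scores with the simulated p53 H-scores (Spearman target 0.85 at cohort
scale) on the ~30% of patients carrying stain data:

```r
stains <- do.call(rbind, lapply(cohort$patients, function(p) {
  if (is.null(p$stain_fractions)) return(NULL)
  data.frame(patient_id = p$patient_id, marker = "p53", p$stain_fractions$p53)
}))
correlate_risk_stains(
  data.frame(patient_id = het$patient_id, heterogeneity_PFS = scores), stains)
#>  marker             model       rho            p  n
#>     p53 heterogeneity_PFS 0.7463054 3.348962e-06 29
```

## Layout

* `R/` — phantom generator, VOI measurements, cross-lesion statistics,
  texture metrics, survival models (`ith_cox` S3 class), agreement/ICC,
  NIfTI/CSV I/O.
* `tests/testthat/` — unit, property and oracle tests per module plus
  end-to-end acceptance checks.
* `vignettes/inter-tumor-heterogeneity.Rmd` — the methods vignette:
  definitions, conventions, generator design, limitations.
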