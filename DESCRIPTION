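Package: ithet
Title: Inter-Tumor Heterogeneity Metrics and Prognostic Models for Multi-Lesion PET/CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies lesion-to-lesion (inter-tumor) heterogeneity in patients
    with multiple co-registered PET/CT lesions. Computes eight conventional
    per-lesion measurements (voxel count, axis lengths, mean HU, SUVmax,
    SUVmean, SUVpeak, TLG), summarises each across a patient's lesions with
    thirteen cross-lesion statistics (104 conventional metrics), and derives
    three CT-texture heterogeneity metrics (cluster site entropy, cluster
    standard deviation, cluster dissimilarity) from GLCM/Haralick features,
    voxel subregion clustering and the grey level distance zone matrix.
    Includes LASSO-Cox prognostic modelling of progression-free and overall
    survival with concordance, Kaplan-Meier/log-rank and time-dependent ROC
    evaluation, Spearman correlation of model risk scores with
    immunohistochemistry H-scores, ICC-based test-retest screening, and a
    synthetic phantom-cohort generator with planted ground truth for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    glmnet,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
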