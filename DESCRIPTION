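Package: vrwma
Title: Wall Motion Abnormality Detection from Volume Renderings of 4DCT
    Left-Ventricular Blood Pools
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects regional left-ventricular wall motion abnormalities (WMA)
    from dynamic volume renderings of ECG-gated cardiac 4DCT blood-pool volumes.
    Provides a seeded synthetic 4D LV phantom with known regional defects, the
    canonical six-view rendering geometry around the LV long axis, a perspective
    ray-casting volume renderer with per-pixel endocardial visibility, quantitative
    ground-truth labeling by regional endocardial shortening (RS_CT, the end-systolic
    to end-diastolic local mesh-area ratio minus one), a frame-feature plus LSTM
    sequence classifier with study-level split and cross-validation plans, and the
    full evaluation arithmetic (confusion matrices, sensitivity/specificity/accuracy,
    Cohen's kappa with 95% confidence intervals, per-view re-binning, LVEF
    stratification, two-proportion z-tests and pairwise chi-squared tests).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    png,
    withr,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
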