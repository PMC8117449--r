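Package: fetdki
Title: Combined Amino-Acid PET and Diffusion Kurtosis MRI Analysis for
    Posttreatment Glioma Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for differentiating glioblastoma tumor
    progression from treatment-related changes by combining dynamic
    O-(2-[18F]-fluoroethyl)-L-tyrosine (FET) PET with diffusion kurtosis
    imaging (DKI). Provides diffusion and kurtosis tensor estimation from
    multi-shell diffusion MRI with Rician noise-bias correction, PET
    tumor-to-brain-ratio analytics and time-activity-curve metrics,
    PET-guided three-dimensional lesion segmentation, histogram-centile
    feature extraction, nonparametric group statistics with Bonferroni
    control, ROC characterization with DeLong AUC comparison, logistic
    biomarker combination, and a composite FET-DKI index classifier.
    Includes synthetic digital phantoms and cohort simulators so the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    minpack.lm,
    pracma,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
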