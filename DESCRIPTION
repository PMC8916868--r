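Package: sweshell
Title: Shear-Wave Elastography Shell Quantification and Improved
    Non-Local-Means Denoising for Skin Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative skin ultrasound in localized scleroderma:
    synthetic layered-skin B-mode phantoms and elasticity-map phantoms with a
    stiffer lesion and a "hard ring" margin; classic non-local-means (NLM)
    denoising and an improved variant combining a cosine patch-similarity
    factor with maximum-a-posteriori regularization solved by ADMM and an
    adaptive Laplacian edge map; image-quality metrics (MSE, PSNR, SSIM) and
    a noise-level sweep harness; shell-ring quantification of elastic modulus
    statistics (Emax, Emean, Emin, Esd) around a lesion mask; dermal thickness
    measurement from B-mode A-lines; and diagnostic statistics (ROC, AUC,
    Youden cutoff, lesion-stage summaries, two-group comparison). Includes two
    end-to-end studies: a denoising benchmark and a simulated shear-wave
    elastography diagnostic study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
LinkingTo:
    Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
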