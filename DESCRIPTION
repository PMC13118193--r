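Package: dkiupgrade
Title: Quantitative Diffusion MRI Analysis of Prostate Cancer Grade Group Upgrading
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of multi-b-value diffusion-weighted
    MRI of the prostate in the context of Gleason Grade Group upgrading from biopsy
    to radical prostatectomy. Implements closed-form forward models and voxelwise
    least-squares fitting of the monoexponential (ADC) and diffusion-kurtosis
    (Dapp, K) signal models, parameter-map assembly with validity masks, ROI-mean
    extraction, simulation of multi-b DWI phantoms with Rician noise and of
    lesion-level cohorts with prescribed group moments, per-stratum group
    comparisons with Holm adjustment and Cohen's d, and single-predictor diagnostic
    evaluation by repeated cross-validated logistic regression with ROC, DeLong
    confidence intervals and Youden-index operating points.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    RNifti,
    pROC,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
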