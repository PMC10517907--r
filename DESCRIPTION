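Package: placentadwi
Title: Placental Virtual MR Elastography and IVIM Diffusion Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of multi-b-value placental diffusion-weighted
    MRI. Computes virtual MR elastography stiffness (mu_diff) from the signal
    log-ratio at two key b-values, fits mono-exponential (ADC), biexponential
    intravoxel-incoherent-motion (f, D, D*) and stretched-exponential
    (DDC, Alpha) diffusion models voxelwise or per ROI, summarizes parameter
    maps over placental regions, quantifies inter- and intra-reader agreement
    (ICC), and carries per-subject summaries through cohort statistics: group
    comparison, multivariable logistic risk modelling, ROC/Youden analysis and
    gestational-age correlation. Includes a calibrated synthetic-data generator
    for signal-level phantoms and parameter-level cohorts.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    minpack.lm,
    pROC,
    MASS,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
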