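Package: hrvscd
Title: Early Sudden Cardiac Death Detection from Heart Rate Variability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated early detection of sudden cardiac death (SCD) risk from
    short-term heart rate variability (HRV). Provides ECG preprocessing
    (wavelet denoising, Pan-Tompkins QRS detection, ectopic-interval
    correction, 2-min segmentation), ensemble empirical mode decomposition
    (EEMD) of RR-interval series, five entropy estimators computed on the
    first intrinsic mode functions (Renyi spectral entropy, fuzzy entropy,
    dispersion entropy, Renyi distribution entropy, improved multiscale
    permutation entropy) together with classical time- and frequency-domain
    HRV indices, multi-method feature ranking, and k-nearest-neighbour
    classification with stratified 10-fold cross-validation. Includes seeded
    synthetic ECG and two-class RR generators so the whole pipeline runs
    without external databases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
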