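Package: vocfinger
Title: Urine-Headspace VOC Fingerprinting for Bile Acid Diarrhoea
Version: 0.1.0
Authors@R:
    person("VOC", "Fingerprint Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classification workflow for urine-headspace volatile organic
    compound (VOC) profiles measured by field asymmetric ion mobility
    spectrometry (FAIMS), a metal-oxide electronic-nose array, and GC-MS,
    aimed at separating bile acid diarrhoea (BAD) from ulcerative colitis
    (UC) and healthy controls. Provides Daubechies-4 wavelet feature
    extraction from concatenated dispersion matrices, within/between-class
    scatter variable selection with a two-dimensional threshold-space
    robustness search, regularized Fisher linear discriminant analysis with
    k-nearest-neighbour leave-one-out reclassification, maximum
    resistance-change e-nose features, cosine-similarity GC-MS marker
    detection against packaged reference spectra, and a deterministic
    synthetic cohort generator so the full pipeline is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
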