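Package: falffdecode
Title: Decoding Eyes-Open and Eyes-Closed Resting States from fALFF Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying whether eyes-closed (EC) versus eyes-open (EO)
    resting states can be decoded from the spatial pattern of the fractional
    amplitude of low-frequency fluctuation (fALFF) of resting-state BOLD
    signals. Provides a seeded synthetic resting-state generator with
    band-limited oscillations, 1/f and white noise, and known condition
    effects; spectral ALFF/fALFF estimation with linear detrending, global-mean
    normalisation, optional volumetric smoothing and ROI aggregation over a
    160-region six-module template; paired Wilcoxon signed-rank feature
    selection under four Z-score criteria; linear support-vector decoding with
    ROC/AUC evaluation; and an end-to-end reproducible pipeline with a
    published 28-region worked example.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
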