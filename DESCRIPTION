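Package: pvcnet
Title: Premature Ventricular Contraction Recognition from Windowed ECG Features
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects premature ventricular contraction (PVC) episodes in
    single-lead ECG recordings. Records are segmented into 20-second windows;
    seven time-domain RR-interval statistics (MeanRR, SDRR, SDSD, rMSSD,
    pRR10, pRR50, max-min ratio) and three QRS morphology features (QRS width,
    QR amplitude, RS amplitude) are extracted per window, min-max normalized,
    and classified as PVC or non-PVC by a two-route one-dimensional
    convolutional neural network trained with Adam. Includes a seeded
    synthetic ECG generator with annotated normal and PVC beats, reading and
    writing of PhysioNet WFDB record triplets (.hea/.dat/.atr), AAMI beat-class
    mapping with the conventional MIT-BIH paced-record exclusions and
    inter-patient train/test partition, a Pan-Tompkins style R-peak detector,
    and per-record precision/recall/F-score evaluation reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    signal
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
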