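Package: ppgbp
Title: Continuous Blood Pressure Waveform Estimation from Photoplethysmography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates continuous arterial blood pressure (ABP) waveforms from
    photoplethysmography (PPG) signals with a 1-D encoder-decoder network that
    uses sparse residual blocks, squeeze-and-excitation attention with
    recurrent (GRU) gating on the skip connections, and deeply supervised
    auxiliary outputs. Includes the full pipeline around the model: readers
    for MATLAB cell-array record containers and CSV records, record filtering,
    spectral baseline removal, zero-phase Butterworth bandpass filtering, peak
    clipping, z-score standardization, windowing and dataset splitting, a
    synthetic paired PPG/ABP generator with per-beat ground truth, training
    with early stopping, and device-grade evaluation: error metrics, British
    Hypertension Society (BHS) grading, AAMI compliance checks and
    Bland-Altman limits of agreement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    arrow,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
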