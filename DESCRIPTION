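Package: fecgsqi
Title: Signal Quality Assessment for Non-Invasive Foetal ECG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the signal quality of multi-channel
    non-invasive foetal electrocardiography (NI-FECG). Provides a synthetic
    abdominal-mixture generator with known maternal and foetal beat
    annotations and controllable foetal signal-to-noise ratio; a
    preprocessing chain (min-max normalization, Butterworth bandpass,
    windowing, short-time Fourier spectrogram images); five QRS detector
    families and annotation matching; template-subtraction/PCA maternal-ECG
    cancellation; the 45 classical foetal signal-quality-index features;
    a multi-path residual convolutional network quality classifier trained
    with Adam on binary cross-entropy; classical machine-learning baselines
    with grid search; and a nested stratified cross-validation harness with
    recording-level majority voting and per-minute error rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    e1071,
    randomForest,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
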