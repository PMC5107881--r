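Package: nirscnn
Title: Channel-Wise CNN Classification and ROI Selection for fNIRS Group Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying group-discriminative measurement channels in
    functional near-infrared spectroscopy (fNIRS) studies. A small
    one-dimensional convolutional neural network is trained from first
    principles on each channel's oxy-hemoglobin time series to classify
    subjects into two groups; channels are ranked by leave-one-out
    cross-validated identification rate and the best channels form the region
    of interest (ROI). Includes a block-design fNIRS simulator with
    physiological confounds, the standard preprocessing chain (low-pass
    filtering, moving average, windowed feature extraction, min-max
    normalization), and interpretability exports of learned kernels and
    pooling-layer activations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
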