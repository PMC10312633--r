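Package: FlySleepLFP
Title: Sleep Stages from Long-Term Multichannel LFP Recordings in Drosophila
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for identifying sleep stages in long-term
    multichannel local field potential (LFP) recordings from the fly brain.
    Provides behavior-based sleep-bout labeling from video movement, detection
    of the polarity-reversal channel from visual-stimulus calibration data,
    reversal-based and bipolar re-referencing, channel-by-frequency spectral
    feature extraction, cluster-based permutation statistics on
    channel-frequency difference maps, classifier-probability sleep staging
    with permutation feature importance, and pose-derived proboscis-extension
    micro-behavior analysis. A synthetic-session generator emulating the
    statistical structure of the recordings makes every stage testable
    without access to raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    signal,
    e1071,
    randomForest,
    pracma,
    EBImage,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
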