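Package: osaconnect
Title: EEG Brain-Connectivity Contrast of Obstructive Sleep Apnea and
    Healthy Sleepers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for separating obstructive sleep apnea
    (OSA) from healthy subjects through EEG brain-connectivity analysis:
    wavelet-packet (db4, level 5) separation of 4-channel sleep EEG into
    the five clinical frequency bands, per-band channel-by-channel
    Pearson correlation of absolute wavelet coefficients, positive-edge
    graph summaries with node degrees and BrainNet Viewer exports, and
    nonparametric (Mann-Whitney-Wilcoxon) group comparison.  Ships a
    synthetic two-group cohort generator with prescribed band-specific
    inter-channel coupling so every stage is verifiable without access
    to polysomnography recordings, plus readers and writers for EDF and
    a columnar text fixture format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
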