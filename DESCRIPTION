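Package: cacti
Title: Calcium Transient Classification Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring per-frame neuronal activity from two-photon
    calcium imaging movies. Includes a ground-truthed simulator of densely
    packed, overlapping somata with linear-rise/exponential-decay transients;
    a masked three-stream movie-patch pipeline with augmentation and
    stratification; a CNN + attention + bidirectional-LSTM per-frame activity
    classifier (and a cell-type variant) implemented in base R; transient-level
    sensitivity/precision/F1 benchmarking; and a correlation-based detector of
    overlap-induced false transients.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tiff,
    yaml,
    zoo,
    mgcv,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
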