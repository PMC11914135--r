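Package: bciparity
Title: Online-Parity Filtering and Classification for P300 RSVP
    Brain-Computer Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares conventional (filter-then-epoch) against online-parity
    (epoch-then-filter) pre-processing for rapid serial visual presentation
    (RSVP) P300 speller calibration data. Provides a synthetic EEG generator
    with N200/P300 event-related potentials, background noise, alpha rhythm,
    power-line interference and blink artifacts; a zero-phase notch plus
    causal Butterworth bandpass filter chain with inquiry buffering; three
    trial classifiers with likelihood outputs (channel-wise PCA + regularized
    discriminant analysis + kernel density estimation, L2 logistic
    regression, and xDAWN + Riemannian tangent-space LDA); balanced accuracy
    and Matthews correlation metrics; a paired sign-flip permutation t-test;
    an online copy-phrase simulation; and an experiment driver that runs the
    full multi-subject comparison, filter-band sweep and statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    signal,
    glmnet,
    jsonlite,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
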