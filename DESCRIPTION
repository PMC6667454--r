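Package: qadecoder
Title: Question-and-Answer Speech Decoding from High-Gamma Neural Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for decoding perceived and produced speech from
    multi-electrode high-gamma (70-150 Hz) cortical activity in an
    interactive question-and-answer setting. Implements the full decoding
    chain: FIR filter-bank extraction of analytic-amplitude high-gamma
    z-score features, PCA-LDA speech event detection with smoothing and
    debouncing, phone-level hidden Markov model Viterbi classification of
    utterances, Bayesian integration of decoded question context into
    answer posteriors, and the associated evaluation metrics (utterance
    error rate, cross entropy, detection score, discriminative power,
    decision finalization times, phone confusions). A synthetic-session
    generator emulates the statistical structure of the task so the whole
    pipeline can be exercised and tested without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
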