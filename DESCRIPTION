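Package: spikemf
Title: Matched-Filter and Neural-Network Detection of Epileptic Spikes in EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage automatic detection of interictal epileptic spikes in
    pediatric electroencephalogram (EEG) recordings. A spike template, built by
    averaging expert-annotated spike segments, drives a normalized matched
    filter that scans each channel with a sliding window and flags windows
    whose similarity to the template exceeds a threshold; near-duplicate
    detections are merged, and each candidate event is then confirmed or
    rejected by a backpropagation multilayer perceptron trained on simple
    statistical window features. Includes readers for EDF and plain-text
    signals, event- and window-level evaluation (sensitivity, specificity,
    precision, threshold sweeps), and a seeded synthetic EEG generator
    (band-limited background rhythm plus injected spike and
    spike-and-slow-wave transients with exact ground truth) so the whole
    pipeline is testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nnet,
    withr
Config/testthat/edition: 3
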