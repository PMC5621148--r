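Package: qrsdetect
Title: Real-Time QRS Detection and R-Point Recognition for Single-Lead ECG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects QRS complexes and recognizes the R point in single-lead
    electrocardiogram (ECG) signals using a low-complexity real-time method: a
    zero-sum enhancement mask that amplifies QRS segments while restraining P
    and T waves and eliminating baseline wander, a four-case crest/trough state
    machine that locates a QRS fiducial point in each refreshed two-second
    window, and a four-template recognition step that localizes the Q, Ra, R,
    and S points and assigns a morphology label per beat.  Includes readers for
    WFDB records and MIT-format beat annotations, an EC57-style beat-by-beat
    evaluator (sensitivity, positive predictivity, detection error rate, with
    ventricular-flutter exclusion and a per-rhythm breakdown), and a seeded
    synthetic single-lead ECG generator with ground truth for the supported
    beat morphologies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
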