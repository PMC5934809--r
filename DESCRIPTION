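Package: ecgflow
Title: Automatic Long-Term ECG Rhythm Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic analysis of long-term single-lead electrocardiogram
    (ECG) recordings: zero-phase band-pass filtering, dynamic-threshold
    artifact masking, mathematical-morphology R-peak enhancement and
    detection, QRS delineation, RR-interval feature extraction, rule-based
    classification of normal beats, atrial and ventricular premature beats,
    bigeminy and trigeminy runs, and normal-beat template matching to
    reconfirm abnormal labels. Includes an annotated synthetic ECG generator
    emulating a bedside patient simulator, beat- and event-level
    sensitivity/specificity scoring, and a command-line pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
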