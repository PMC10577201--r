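Package: owdet
Title: Open-World Plant Disease Detection Protocols, Metrics and a Desk-Scale Detector
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for the open-world, incrementally updated plant-disease
    detection paradigm: task-sequenced class schedules with known/unknown
    bookkeeping, COCO-dialect annotation and detection I/O, unknown-aware
    pseudo-labeling of region proposals, a class-agnostic bounding-box
    regression codec, energy-score based unknown identification with
    validation-fitted known/unknown energy densities, balanced exemplar
    replay against catastrophic forgetting, and the open-world evaluation
    metrics (previous/current/known mAP at IoU 0.5 with 11-point
    interpolation, Unknown Recall, Absolute Open-Set Error). A seeded
    synthetic lesion-scene generator and a CPU-scale two-stage detector
    analogue exercise the full paradigm end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
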