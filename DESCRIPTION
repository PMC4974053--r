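Package: mgtask
Title: Analysis of Trial-Structured Calcium Imaging from a Memory-Guided
    Go/No-Go Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end, seeded analysis pipeline for two-photon calcium
    imaging recorded during a memory-guided go/no-go visual discrimination
    task with variable delays. Includes a synthetic-data generator (trial
    tables, dF/F trace tensors built from six response archetypes with
    GCaMP6s-like kinetics, imaging movies with ground-truth ROIs, and
    behavior-camera frames), behavioral statistics (per-delay hit/false-alarm
    rates, d-prime, session quality control, photoinhibition comparisons),
    movie preprocessing (cross-correlation registration, activity-map ROI
    segmentation, neuropil-corrected fluorescence, dF/F, duplicate removal),
    trial-locked response significance testing and archetype clustering,
    selectivity/latency/delay-modulation indices, ideal-observer auROC
    population decoding with permutation nulls, targeted dimensionality
    reduction onto orthogonal stimulus and choice axes, and behavior-video
    movement difference maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    EBImage,
    jsonlite,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
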