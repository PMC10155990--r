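Package: odplast
Title: Ocular Dominance Plasticity Analysis for Two-Photon Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for measuring how monocular deprivation during
    the critical period alters binocularity, orientation preference, and
    spatial-frequency tuning of neurons in mouse binocular visual cortex.
    Covers stimulus-schedule construction, neuropil-corrected dF/F and spike
    inference from GCaMP6s traces, reverse-correlation response mapping with
    three-criterion responsiveness classification, vector-average orientation
    and log-weighted spatial-frequency tuning metrics, ocular dominance index
    and binocular-matching statistics, longitudinal ROI matching with
    category-transition tables, and group-level summaries. Includes a
    synthetic-data generator with ground-truth tuning so the full pipeline is
    testable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    mgcv
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
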