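Package: musclepdff
Title: Water-Fat MRI Simulation, PDFF Mapping and Muscle Composition Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative muscle composition analysis with
    chemical-shift-encoded MRI. Simulates multi-echo bipolar gradient-echo
    acquisitions of digital muscle phantoms with known ground truth, performs
    complex-based water-fat separation (variable projection over a field-map x
    R2* search with local refinement) to produce proton density fat fraction
    (PDFF) and T2* maps, extracts whole-muscle and regional
    (proximal/middle/distal) PDFF and volume metrics from segmentation masks,
    computes longitudinal maximum-change statistics and Fearon cachexia
    classification, and runs a cohort-level correlation battery including
    age-controlled partial correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    nortest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
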