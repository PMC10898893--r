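Package: oncovalue
Title: ASCO Value Framework Scoring for Advanced-Disease Oncology Regimens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements the American Society of Clinical Oncology (ASCO)
    advanced-disease value framework as a reproducible scoring pipeline:
    clinical-benefit points from trial efficacy statistics (hazard ratios,
    medians, response rates), toxicity points from graded adverse-event
    frequencies, bonus points (tail of the survival curve, palliation,
    quality of life, treatment-free interval), the composite net health
    benefit (NHB), monthly drug-acquisition cost from dosing and regulated
    price per mg, and cost per NHB point.  Ships the published worked
    examples for enzalutamide and apalutamide in non-metastatic
    castration-resistant and metastatic hormone-sensitive prostate cancer
    as validated fixtures, a synthetic two-arm trial simulator with known
    ground truth, and Monte-Carlo propagation of hazard-ratio confidence
    intervals into NHB and cost-per-point intervals.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
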