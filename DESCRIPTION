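Package: artix
Title: Finger-Redness Quantification of Raynaud's Phenomenon from Hand Photographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts RGB photographs of the dorsum of the hands into a
    per-timepoint finger-redness score (ARTIX) for the assessment of
    Raynaud's phenomenon. Provides hand segmentation (a trainable
    pixel-classifier segmenter plus a deterministic classical fallback),
    landmark-driven per-finger mask extraction with thumb exclusion,
    masked Gaussian smoothing with quartile-based colour statistics, the
    standardized seven-timepoint cold-challenge session model with a
    thermography reference aggregate, and the validation statistics used
    to compare patients with healthy controls (normality-routed group
    comparisons, contingency and McNemar tests, collinearity-screened
    multilinear regression, and per-timepoint ROC analysis). A synthetic
    hand and cohort generator supplies ground-truth masks, landmarks and
    cold-challenge sessions so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    pROC,
    car,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
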