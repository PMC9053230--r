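Package: marrowhct
Title: Automated Bone Marrow Cytology via Histograms of Cell Types
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: An end-to-end, testable framework for automated bone marrow
    aspirate cytology. Provides grid-based region-of-interest (ROI) tile
    selection over whole-slide images, a pluggable cell detection and
    classification backend contract (with a reference blob detector),
    accumulation of per-tile Histograms of Cell Types (HCT) into a
    chi-square-converged Integrated HCT yielding a nucleated differential
    cell count report with myeloid-to-erythroid ratio, the full
    object-detection evaluation suite (11-point interpolated average
    precision, mean AP, F1, log-average miss rate, confusion matrices,
    Cohen's kappa), a rare-class-targeted active-learning annotation loop,
    and a synthetic slide generator with known ground truth so that every
    stage can be exercised and validated without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
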