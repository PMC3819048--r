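Package: csdread
Title: Current Source Density Index of Extended-Text Reading Comprehension
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives a current-source-density (CSD) index of extended-text
    reading comprehension from event-related potentials (ERPs). Implements
    epoch extraction and post-onset baselining of target-word ERPs, the
    spherical-spline surface-Laplacian (CSD) transform, scrambled-minus-
    comprehension difference CSDs, a two-stage random-forest titration over
    scalp sites and overlapping time bins with permutation-null significance,
    exact chance combinatorics for a multi-select comprehension test, and
    downstream index statistics (confidence-ellipse correlations, mixed
    ANOVAs, condition-order controls). Ships a synthetic-cohort generator
    with known ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    ranger,
    stats,
    utils,
    yaml
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
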