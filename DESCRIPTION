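Package: ssmdscreen
Title: SSMD-Based Analysis of Single-Well Plate Screens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for phenotypic high-throughput screens run
    with one specimen per well and no within-plate replication, as in
    fluorescence-readout zebrafish compound screens. Scores every well with
    the single-well strictly standardized median difference (SSMD*) against
    a robust plate-wise reference, calls inhibitor/activator hits with
    two-replicate concordance, computes control-based plate quality control
    (sensitivity, specificity, control variability), summarizes dose-response
    series with a permutation trend test, and generates synthetic screens
    with planted ground truth so the whole pipeline can be validated without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
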