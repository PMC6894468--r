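Package: dupbehav
Title: Duplication of Behaviour Analysis for Time-Use Diaries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the Duplication of Behaviour analysis for
    time-use recall data: dichotomization of diary records into binary
    person-by-activity engagement matrices, duplication (sharing) tables,
    the duplication coefficient D, expected co-engagement values and their
    Spearman fit, deviation and partition detection, and Mean Absolute
    Deviation (MAD) segmentation of engager demographics. Includes a
    synthetic diary generator with controllable pairwise dependence and
    demographic skews, re-keyed published summary tables for benchmarking,
    and report-writing entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
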