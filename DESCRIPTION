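Package: ShadowCount
Title: Time-Lapse Shadow Image Analysis for Rapid Colony Enumeration
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Detects, tracks and counts microbial colonies in time-lapse
    shadow-image stacks of agar plates. Colonies are segmented in each
    frame, linked across frames so that growing colonies are separated
    from static debris, and counts are preserved through colony fusion.
    The per-frame colony-count series is screened with steady-level
    criteria to produce a rapid count that can be compared with the
    count confirmed at the end of the full culture time, including
    log-log regression and paired t-test equivalence statistics across
    plates. A synthetic plate simulator with known ground truth, and a
    retrievable per-colony image store, support validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff,
    png,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
biocViews: CellBasedAssays, Software, Visualization
RoxygenNote: 7.3.3
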