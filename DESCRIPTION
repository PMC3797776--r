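Package: glaucodrive
Title: Driving-Simulator Performance and Visual-Field Analysis for Glaucoma Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for fixed-base driving-simulator studies of
    drivers with glaucomatous visual field loss. Computes filtered
    steering-activity metrics and the standard deviation of lateral position
    from 60 Hz vehicle traces, obstacle-avoidance distances and collision
    flags, peripheral letter-detection scores and reaction times,
    dispersion-based (I-DT) eye fixations with blink-aware preprocessing and
    area-of-interest dwell, and integrated visual fields with quadrant
    sensitivity-loss percentages from Humphrey 24-2 perimetry. Includes a
    synthetic-cohort simulator (visual fields, closed-loop driving traces,
    letter responses, gaze streams, workload ratings) so every stage of the
    pipeline can be exercised and validated without participant data, and
    group statistics (Welch t, paired t, Spearman) with table-style reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
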