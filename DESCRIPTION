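Package: stpdosim
Title: Single-Time-Point Dosimetry for Lu-177 Radiopharmaceutical Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for image-based internal dosimetry of Lu-177 PSMA
    radioligand therapy with reduced imaging schedules. Fits monoexponential
    time-activity curves per volume of interest (VOI), computes the
    multiple-time-point (MTP) reference time-integrated activity (TIA) and two
    single-time-point (STP) estimators (the Hanscheid approximation and a
    prior-information estimator that reuses the first-cycle effective
    half-life), and provides the cohort-level method-comparison statistics
    used to judge STP feasibility: percentage differences, Bland-Altman
    summaries, exact Wilcoxon signed-rank tests, coverage tables and
    validity-window tables. Includes a seeded synthetic-cohort simulator
    calibrated to published Lu-177-PSMA-617 population kinetics, plus a
    voxel-phantom path exercising threshold segmentation and SUV conversion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
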