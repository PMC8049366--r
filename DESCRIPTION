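Package: tracerdose
Title: Whole-Body Kinetics and Internal Radiation Dosimetry for PET
    Radiotracers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for first-in-humans biodistribution and dosimetry
    analyses of short-lived PET radiopharmaceuticals. Fits per-organ
    time-activity curves with sums of exponentials, integrates them to
    time-integrated activity coefficients (residence times) including a
    dynamic urinary bladder voiding model, and turns residence times into
    MIRD-style organ dose-equivalents and an ICRP-103 effective dose via a
    pluggable S-value table. Also covers the blood side (plasma-to-blood
    partitioning, plasma protein binding, radio-HPLC parent-fraction
    modelling, metabolite-corrected tail pharmacokinetics) and ships a
    calibrated whole-body kinetics simulator with closed-form ground truth
    so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
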