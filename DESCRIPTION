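Package: trigdiag
Title: Trigeminal Electrophysiology Diagnostics for Orofacial Pain Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for electrophysiological differential
    diagnosis between temporomandibular disorders (TMD) and other
    orofacial pain. Extracts peak-to-peak amplitudes from averaged
    jaw-jerk reflex and trigeminal-root motor-evoked-potential EMG
    traces, computes bilateral asymmetry ratios with the reference side
    in the numerator, derives percentile-based screening cutoffs from a
    control cohort, and applies a two-step 2x2 matrix classifier
    separating organic trigeminal damage, TMD, and non-TMD orofacial
    pain. Includes moment-matched skew-normal cohort simulation for
    end-to-end validation without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    MASS,
    stats,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
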