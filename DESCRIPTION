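Package: qrsmatch
Title: Binary QRS Template Matching for ECG-Based Identity Verification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements a 12-lead electrocardiogram (ECG) biometric
    verification pipeline built on binary QRS template matching. Average
    heartbeats from two recording sessions are resampled to a 1 ms grid,
    aligned to a lead-I reference pattern by maximal cross-correlation, and
    100 ms QRS windows are extracted synchronously in all 12 leads. Each
    pair-normalized pattern is approximated by a 100 x 80 binary
    time-amplitude occupancy matrix, from which two matching features per
    lead are computed: the matching time tEQU (percentage of 1 ms steps at
    which the tolerance bands of the two patterns overlap) and the mismatch
    area aDIF (normalized area enclosed between non-overlapping amplitude
    bands). A stepwise-selected linear discriminant verifier is trained on
    balanced same/different identity pairs, calibrated at the equal error
    rate operating point of the training ROC, and evaluated by true
    acceptance, rejection and verification rates, with cohort analyses by
    sample size, gender, age and heart rate. A seeded synthetic generator of
    paired-session 12-lead average beats makes the full pipeline testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
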