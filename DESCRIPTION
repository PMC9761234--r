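Package: rmnihl
Title: Diagnosis of Noise-Induced Hearing Loss from Military Service Audiograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the rM-NIHL method for diagnosing noise-induced
    hearing loss (NIHL) sustained during military service from pure-tone
    audiograms, together with the original M-NIHL method it revises.
    Provides age-associated hearing loss (AAHL) reference surfaces, the
    notch-depth statistic Mag(Notch) and high-frequency excess statistic
    Mag(ExcessHF), ear- and individual-level diagnosis under either-ear,
    both-ears and each-ear rules, diagnostic performance evaluation
    (sensitivity, specificity, d-prime), ROC-style criterion sweeps, the
    balanced criterion-selection procedure, and a synthetic audiogram
    cohort simulator for testing without claimant data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
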