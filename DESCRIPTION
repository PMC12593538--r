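Package: smallfof
Title: Small-Field Output Factors and Effective Spot Size Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for small-field dosimetry of rectangular MLC-shaped
    photon fields following the TRS-483 code of practice: field output
    factor (FOF) determination with detector output correction factors
    (OCF), equivalent square field size for elongated fields via an
    empirical generalization of the Sterling formula, beam-profile
    metrics (FWHM and 20-80% penumbra), a Gaussian source-occlusion
    forward dose engine for synthetic commissioning data, and a
    sequential grid-search procedure that tunes the per-axis effective
    spot size (ESS) of a treatment planning system beam model against
    measured output factors of elongated fields.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
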