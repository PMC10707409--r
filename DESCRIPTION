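Package: ceuskinetics
Title: Quantification of Contrast-Enhanced Ultrasound Time-Intensity Curves
    for Adnexal Tumour Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying contrast-enhanced ultrasound (CEUS) exams of
    adnexal tumours through the fractional colour-Doppler area (%CDA).
    Segments colour-overlay pixels inside a region of interest to extract
    time-intensity curves, computes wash-in/wash-out curve features and the
    integral perfusion statistic S, classifies lesions by S bands, and runs
    the associated statistical battery (Cochran-Cox approximate test for
    unequal variances, normal-approximated Mann-Whitney U, chi-square
    independence, Pearson correlation). Includes a synthetic-exam generator
    that reproduces published group-level kinetics and a null association
    between S and immunohistochemical markers (CD34, CD105, bcl-2), so the
    full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
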