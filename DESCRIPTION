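Package: lpmosaic
Title: Validation of Low-Pass Sequencing PGT-A for Chromosomal Mosaicism
    and Segmental Aneuploidy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates per-bin read-count profiles of whole-genome-amplified
    multi-cell biopsies reconstructed as mixtures of karyotyped cell lines,
    and implements the copy-number analysis used to validate two
    low-pass-sequencing preimplantation genetic testing (PGT-A) platforms
    for chromosomal mosaicism: GC and in-silico-reference normalization, a
    Gaussian-likelihood copy-number state caller with median fallback, a
    chromosome-read-fraction baseline-ratio caller, euploid-range
    calibration, mosaicism classification and limit-of-detection
    determination, run-length segmental-deletion detection, and
    concordance statistics (sensitivity and specificity with exact
    Clopper-Pearson confidence intervals).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
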