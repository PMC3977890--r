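Package: ihcval
Title: Reproducibility Validation for Ordinal Immunohistochemistry Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Validation toolkit for ordinal immunohistochemistry (IHC)
    scoring assays, built around the reading of androgen-receptor staining
    intensity in circulating tumour cells. Quantifies inter- and
    intra-operator reproducibility with Cohen's kappa and beta-content
    gamma-confidence tolerance intervals (BCTI) under a modified
    incurred-sample-reanalysis (ISR) design, constructs per-category
    accuracy profiles that separate operator bias from imprecision, checks
    repeat-analysis differences against the +/-30 percent total-error
    benchmark, and ships a seeded simulator of two-operator scoring studies
    so every stage can be exercised without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
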