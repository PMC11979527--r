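Package: tdpddi
Title: Drug-Drug Interaction Signal Detection for Torsades de Pointes
    from Spontaneous Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Disproportionality analysis of case-level spontaneous adverse
    event reports (FAERS-like) for drug-drug interaction (DDI) signal
    detection, with torsades de pointes as the motivating adverse event.
    Implements single-drug reporting odds ratios and four frequency-
    statistical DDI models on the 4-by-2 drug-pair contingency table (the
    Omega shrinkage measure, a signed Yates-corrected chi-square against
    the same no-interaction baseline, the combination risk ratio, and the
    additive risk contrast), an all-four consensus rule, pairwise
    inter-model agreement (Cohen kappa with proportionate positive and
    negative agreement), verification of detected pairs against DDI
    reference compendia including negative-DDI identification, and a
    seeded synthetic report generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
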