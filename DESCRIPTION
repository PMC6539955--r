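Package: flavoqsar
Title: Flavonoid P-Glycoprotein Inhibition: Reversal Folds and 2D-QSAR
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for a flavonoid multidrug-resistance reversal
    study in P-glycoprotein-overexpressing KB/MDR1 cells. Computes reversal
    and cross-resistance folds from daunorubicin cytotoxicity IC50 tables,
    classifies compounds as potential P-gp inhibitors or activators, fits a
    four-descriptor 2D-QSAR model of IC50 by ordinary least squares and by
    NIPALS partial least squares, and validates it with leave-one-out Q2,
    external test-set prediction and reliability gates. Ships the in-study
    compound, cytotoxicity and descriptor tables as plain-text fixtures,
    estimates IC50 from dose-response plates by four-parameter-logistic
    fitting, and includes seeded synthetic-data generators (correlated
    descriptor matrices, linear responses, decoy descriptor pools, viability
    plates) so every stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    ggplot2
Config/testthat/edition: 3
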