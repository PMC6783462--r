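Package: dosescreen
Title: Dose-Response Modeling of Cell-Line Drug Screens with Nonlinear
    Mixed Effects and Outlier Cell-Line Detection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for modeling in vitro drug-response panels of cancer
    cell lines. Fits four-parameter and three-parameter logistic and
    linear dose-response curves per cell line by Nelder-Mead least
    squares, selects the best functional form by AIC, fits a joint
    nonlinear mixed-effects model per cancer type and drug with random
    effects on log-EC50 and slope via an alternating penalized
    least-squares / linearized maximum-likelihood scheme, standardizes
    the EC50 random effects across drugs, and flags cell lines that are
    consistently drug-sensitive or drug-resistant using
    confidence-boundary and distribution rules. Includes a synthetic
    panel generator emulating large pharmacogenomic screens so the whole
    pipeline can be exercised with known ground truth, and Spearman
    concordance summaries within and between studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    nlme
Config/testthat/edition: 3
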