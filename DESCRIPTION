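Package: seromarker
Title: Tumour-Derived Serum Biomarker Discovery and Diagnostic Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cross-omics discovery and clinical evaluation of tumour-derived
    serum biomarkers, built around the paired tissue-transcriptome /
    serum-proteome design used in lymphoma biomarker studies. Provides
    per-layer differential expression with across-subject protein-mRNA
    Spearman correlation and an intersection criterion for tumour-derived
    candidates; an absolute kappa/lambda light-chain restriction score for
    monoclonality; ROC analysis with Youden and minimal-AIC cutoffs,
    restricted cubic spline linearity testing and ordinalization of a
    continuous marker; propensity-score matching with balance diagnostics,
    multivariate logistic modelling with AIC-guided predictor inclusion, a
    points-based nomogram and bootstrap calibration; and seeded synthetic-data
    generators emulating the paired-omics and case-control structure so the
    whole chain is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
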