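Package: atcmarkers
Title: Marker Discovery and Diagnostic Validation for Anaplastic Thyroid Carcinoma
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An analysis pipeline for nominating and validating
    tumor-exclusive expression markers of anaplastic thyroid carcinoma
    (ATC). From a multi-class RNA-seq count matrix it performs TMM
    normalization, negative-binomial exact testing of ATC against all
    other classes, a de novo expression screen (near-zero expression
    outside ATC, strong induction in ATC) ranked by relative standard
    deviation, and preranked gene-set enrichment analysis. From
    immunohistochemistry cohort tables it computes Histoscores,
    positivity calls, pooled contingency tables and diagnostic accuracy
    (sensitivity, specificity, predictive values, diagnostic odds ratio)
    with confidence intervals. A synthetic-cohort generator provides
    inputs with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite
Config/testthat/edition: 3
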