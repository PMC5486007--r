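Package: folliclass
Title: Expression Markers and Classification of Follicular Thyroid Tumours
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for discriminating follicular thyroid carcinoma
    (FTC) from follicular thyroid adenoma (FTA) from quantitative real-time PCR
    and microarray-style expression data. Implements efficiency-corrected
    relative quantification (Pfaffl method) with geNorm reference-gene
    stability ranking, extreme-outlier screening, per-gene differential
    expression with Benjamini-Hochberg false discovery rate control and
    two-way ANOVA adjustment for the oncocytic (Hurthle cell) feature,
    cross-study vote-counting meta-analysis of published gene lists, and a
    diagonal linear discriminant analysis (DLDA) classifier evaluated by
    doubly nested leave-one-out cross-validation with exact binomial
    confidence intervals and ROC analysis. A synthetic-data module generates
    qPCR, expression-matrix and multi-study gene-list inputs with known
    ground truth so that every stage of the pipeline is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    car,
    pROC,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
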