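Package: pathmarker
Title: Diagnostic Marker Discovery from Differential Expression and Pathway Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening candidate diagnostic marker genes from bulk
    RNA-seq count data by combining negative-binomial exact-test differential
    expression, gene-set over-representation analysis, KGML (KEGG Markup
    Language) pathway parsing, multi-pathway gene interaction network
    construction with degree-based hub extraction, and a linear maximum-margin
    classifier with stratified cross-validated ROC/AUC evaluation. Includes a
    synthetic-data module that generates negative-binomial count matrices with
    planted differentially expressed genes and schema-valid KGML pathway files
    with known hub structure, so that every pipeline stage can be exercised and
    validated against ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    xml2,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    e1071,
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
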