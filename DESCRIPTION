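Package: alupipe
Title: Alu Element Methylation, Expression and Enrichment Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated analysis of Alu (SINE) retrotransposons in blood
    transcriptomes and lymphoblastoid cell lines: presence filtering and
    t-test/Bonferroni calling of differentially expressed genes, Fisher
    exact-test enrichment of Alu-inserted genes stratified by insertion type
    and regulation direction, cross-study reproducible gene sets, COBRA
    (combined bisulfite restriction analysis) quantification of AluS
    methylation levels and two-CpG patterns from gel band intensities,
    2^-ddCt relative quantification of AluS expression from qPCR Ct tables,
    and methylation-expression correlation within phenotypic subgroups.
    Includes seed-reproducible synthetic-data generators with planted ground
    truth for every input so the whole workflow is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
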