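Package: phycomet
Title: Comparative Metabolic Pathway Completeness and Gene Duplication
    Analysis for Algal Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative metabolic reconstruction across algal
    genome and transcriptome assemblies from KEGG Orthology (KO)
    annotations. Parses KEGG-module-style boolean block definitions,
    grades module completeness per assembly on the five-level scale
    (complete to absent) with KO-step re-grading of partial protein
    complexes, compares completion rates between taxonomic classes,
    selects variable modules by cross-class standard deviation, computes
    phi coefficients between KO/block presence and taxonomic grouping,
    aggregates OrthoFinder-style gene duplication events with functional
    annotations on species-tree nodes, applies BUSCO-based assembly
    quality gates, parses RepeatMasker summary tables, and generates
    fully synthetic study fixtures with controlled statistical structure
    for pipeline testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    car,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
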