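Package: markerdiv
Title: Dominant-Marker Diversity, DNA Barcoding and Expression
    Characterization of Plant Accessions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the desk-scale genetic characterization of small
    panels of plant accessions scored with dominant molecular markers
    (ISSR, SCoT, SDS-PAGE protein profiles). Computes per-primer
    informativeness statistics (polymorphism information content,
    effective multiplex ratio, marker index, resolving power, percent
    polymorphism) from binary band matrices, builds similarity-based
    UPGMA dendrograms with Newick export, performs principal component
    analysis and heatmap scaling, supports DNA-barcode workflows
    (GC content, pairwise identity, p-distance, bootstrapped UPGMA
    trees), quantifies relative gene expression by the Livak 2^-ddCt
    method, and runs replicate-trait statistics (one-way ANOVA, Duncan's
    multiple range letters, Pearson correlation matrices). Seeded
    synthetic-data generators emulate the statistical structure of a
    three-accession diversity study so every pipeline stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
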