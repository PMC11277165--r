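Package: coicoii
Title: Structural Haplotyping of the Honey Bee COI-COII Mitochondrial Intergenic Region
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for the hypervariable tRNA-leu / COI-COII intergenic
    region of Apis mellifera mitochondrial DNA. Decomposes E2/H2 amplicons into
    their structural elements (P, P0, P1 and tandem Q units), calls the A/M/C
    evolutionary lineage from the structure, simulates the DraI PCR-RFLP test in
    silico, collapses sequences into haplotypes with catalog matching and
    rule-based nomenclature, re-codes alignment gaps into surrogate bases so that
    indels are counted rather than masked, and builds one median-joining haplotype
    network per structure class. Includes a seeded synthetic-population generator
    with replayable mutation logs so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
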