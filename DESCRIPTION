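Package: haplodx
Title: DNA Barcode Lineage Delimitation and Diagnostic qPCR Assay Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for delimiting insect lineages from DNA barcode
    alignments (CO1/ITS2) and designing diagnostic real-time PCR assays
    against them. Covers alignment trimming to an overlapping core,
    haplotype collapsing, Tamura-Nei distances with neighbor-joining trees
    and jackknife branch support, statistical-parsimony haplotype networks
    with step-path metrics, SNV-density window scanning with multi-criterion
    TaqMan primer/probe design under nearest-neighbor and salt-adjusted GC
    melting-temperature models, in-silico specificity screening against a
    sequence panel, and RFU/Cq/delta-Cq positive-call logic with
    standard-curve analysis. Seeded synthetic-data generators with planted
    haplotype structure make every stage testable without sequence
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    phangorn,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
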