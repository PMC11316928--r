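Package: cgkit
Title: Comparative Genomics Toolkit: Synteny, Map-Based Scaffolding, and
    Genome-Build Quality Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated toolkit for comparative genomics and genome-build
    quality control. Infers synteny blocks from gene-anchored alignment hits
    using C-score filtering, proximal-duplicate removal, and rank-space
    chaining; orders and orients assembly scaffolds against weighted genetic
    or comparative maps with a genetic algorithm and reports per-chromosome
    concordance (Spearman's rho), writing AGP and pseudo-chromosome FASTA;
    surveys genomes from k-mer spectra via a negative binomial mixture model
    and a simpler three-class peak model; evaluates assembly concordance with
    linkage-disequilibrium and Hi-C contact heatmaps; and analyses pedigrees
    (gene-dropping inbreeding coefficients, parentage) and binned copy-number
    landscapes. Includes seeded synthetic-data generators with planted ground
    truth for every input the toolkit consumes, and a hierarchical
    module/script/action command-line dispatcher.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    pracma,
    Biostrings,
    IRanges
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
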