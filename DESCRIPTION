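Package: methdiverge
Title: Comparative Methylome Divergence Analysis for Whole-Genome
    Bisulfite Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative analysis of DNA methylomes across
    closely related species and tissues from whole-genome bisulfite
    sequencing (WGBS) cytosine reports. Builds SNP-corrected reference
    genomes for bisulfite read mapping, loads and destrands per-CpG
    methylation counts, calls differentially methylated regions (DMRs)
    with a replicate-aware beta-binomial test, classifies DMRs into
    species-specific and multi-tissue sets, measures permutation-based
    observed/expected enrichment of DMRs in genomic features
    (promoters, CpG islands, transposable elements) and transposon-age
    profiles, and integrates methylation with gene expression (putative
    functional DMRs, methylation-expression binning and correlation,
    methylome clustering). A synthetic-data module simulates genomes,
    annotations, methylomes and expression with machine-readable planted
    truth so that every stage is verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    methods,
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    ape,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
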