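Package: mitoscan
Title: Genome Scans for Natural Selection on Mitonuclear-Interacting Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Windowed population-genetic scans for natural selection on
    autosomally encoded genes whose products interact with mitochondrial
    DNA, RNA, or protein (N-interact genes: OXPHOS, mitochondrial
    aminoacyl-tRNA synthetases, mitoribosomal proteins, mtDNA replication
    factors). Computes per-window F_ST (Weir-Cockerham or Hudson),
    nucleotide diversity of polymorphic sites, and Tajima's D from diploid
    VCF genotypes; calls runs of homozygosity with a two-state hidden
    Markov model; fits interaction linear models of each statistic on the
    N-interact indicator and gene number with block-bootstrap standard
    errors; runs one-sided permutation tests, Cook's-distance outlier
    excess tests, Nei-Gojobori counting dN/dS comparisons against a
    random gene background, and Patterson's D (ABBA-BABA) introgression
    tests; and combines comparisons with Fisher's method. A synthetic-data
    generator with planted selection signatures, homozygous tracts, omega
    differences, and four-taxon introgression makes the whole pipeline
    testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    vcfR,
    ape,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    IRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
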