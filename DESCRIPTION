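Package: pirkit
Title: Simulation and Analysis of Slicer-Triggered piRNA Biogenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying PIWI-slicer-triggered piRNA biogenesis with
    small RNA sequencing data. Simulates an artificial piRNA precursor
    carrying perfectly complementary binding sites for guide piRNAs, the
    cleavage-fragment read classes that slicing produces (secondary piRNAs,
    phased trail piRNAs, 16-nt by-products, maximum-length pre-piRNA
    intermediates and contaminating microRNAs), and sequencing-ready FASTQ
    libraries with ground-truth labels. Implements the downstream
    statistics used to characterise such libraries: adapter trimming and
    demultiplexing, Hamming-distance alignment with seed-region mismatch
    exclusion, 5'/3'-end distance profiles around target sites, product
    classification, the ping-pong distance score, read-count
    normalisations, sense/antisense annotation, 5'-end sharing
    classification, Pearson-correlation comparison of piRNA profiles,
    nucleotide composition and signed consensus coverage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
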