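Package: syntfind
Title: Multi-Genome Synteny Detection with Bloom-Filter-Guided Minimizer Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Alignment-free detection of macrosynteny blocks shared by two or
    more genome assemblies. A cascading Bloom filter restricts minimizer
    sketches to k-mers common to all genomes; minimizers shared by, and unique
    within, every genome form an undirected adjacency graph whose simplified
    linear paths become multi-genome synteny blocks. Blocks are oriented,
    broken at contig boundaries and putative large indels, refined over
    successive rounds of decreasing window size, size-filtered, and merged
    when collinear. Includes a structural-rearrangement simulator with
    ground-truth coordinate lift maps and evaluation statistics (synteny
    coverage, block NG50, block accuracy).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    igraph,
    data.table,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
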