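Package: fospool
Title: Design, Simulation and Quality Control for Fosmid Pool Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for fosmid-pool (FP) genome sequencing projects:
    closed-form pool-design models (within-pool overlap probability,
    sequencing depth, Lander-Waterman novelty), a synthetic generator for
    genomes, repeat libraries, fosmid pools and paired-end reads, a
    self-contained seed-and-extend local aligner with an exact
    Smith-Waterman oracle and BLAST-style tabular I/O, vector-end
    detection and trimming with clone-count estimation from vector/insert
    junction reads, two-round contamination screening, and repeat
    resolution, genome saturation and assembly-efficiency statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp (>= 1.0.0),
    Biostrings,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    jsonlite
SystemRequirements: C++17
Config/testthat/edition: 3
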