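Package: mastercircle
Title: Assembly and Comparative Analysis of Circular Organellar Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for short-read assembly and comparative
    analysis of circular plant organellar genomes (chloroplast and
    mitochondrial DNA). Implements an offset-bounded exact-overlap
    assembler with paired-read scaffolding, circular closure and
    pileup-based polishing; a read-preprocessing trim-and-cut step for
    converting long reads into dense short fragments; coverage and
    insert-midpoint assembly diagnostics with breakpoint detection and
    AT-rich replication-origin scanning; repeat discovery on circles with
    prediction of recombination-derived subcircles and isomeric circles;
    per-gene nucleotide and amino-acid divergence statistics based on
    pairwise percent identity; C-to-U RNA-editing application and
    pileup-based confirmation with codon-usage accounting; and RPKM
    expression summaries with fold-change flags. Ships a deterministic
    synthetic-data generator for circular genomes with planted repeat
    architecture, simulated paired-end and mate-pair libraries, and
    edited-transcript reads, used as the test substrate throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
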