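Package: mitochip
Title: Screening Transcription Factor Occupancy on the Mitochondrial Genome
    from Strand-Specific ChIP-seq
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating putative nuclear transcription factor
    occupancy over a circular (mitochondrial) genome from ChIP-seq
    alignments restricted to that contig. Provides a deterministic
    read simulator for circular genomes with planted occupancy sites and
    D-loop-like symmetric artifacts, k-mer self-mapping mappability
    tracks, strand-specific full-coverage and base-resolution 5'-end
    tracks, a strand-asymmetry screen that separates genuine punctate
    occupancy (plus/minus 5'-end summits separated by the library
    fragment length) from strand-symmetric artifacts, a BPNet-style
    dilated convolutional sequence-to-profile model with multinomial
    profile loss used as corroborating evidence, and cross-dataset
    aggregation of calls into orthogonal-evidence tiers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
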