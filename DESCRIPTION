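Package: codonmotif
Title: DNA Motif Distribution Analysis on Bacterial Chromosomes Using a
    Codon-Redundancy Null Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies over- and under-representation of short DNA motifs in
    protein-coding regions of bacterial genomes. The null model is the coding
    flexibility of the proteome: every position where synonymous codon choice
    could spell the motif is a potential site, with a realization probability
    estimated from genome-wide in-frame codon n-gram frequencies conditioned
    on the encoded peptide. Observed motif counts are scored against the
    resulting Poisson-binomial distribution to yield per-gene, per-gene-set
    and sliding-window z-scores, and chromosome-scale biases (leading/lagging
    strand, coding/template strand, origin/terminus half, replichore, gene
    subset) are tested by Monte-Carlo randomization. Includes generators for
    synthetic coding sequences with controlled potential and realized motif
    counts for calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ggplot2,
    rlang,
    jsonlite,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
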