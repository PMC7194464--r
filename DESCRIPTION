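Package: phasilens
Title: Small-RNA Silencing Inference: MIRNA Annotation, Pseudo-Degradome
    Slice-Site Detection and 21-nt phasiRNA Phasing
Version: 0.1.0
Authors@R:
    person("phasilens", "developers", email = "phasilens@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for inferring miRNA-directed
    post-transcriptional silencing from small-RNA sequencing libraries:
    adapter trimming, read collapsing and reads-per-million normalisation;
    MIRNA hairpin locus annotation from genome-mapped sRNA clusters using
    base-pair-maximisation folding and duplex criteria (star read,
    two-nucleotide 3' overhangs); miRNA target-site complementarity scoring
    with pseudo-degradome T-plot construction and cleavage-category
    classification; 21-nt phasiRNA register assignment and phase scoring
    anchored at detected slice sites; classification of non-templated 3'
    uridylation; locus expression and splice-junction extraction from SAM
    alignments with the associated summary statistics; and codon-level
    comparison of coding sequences. A bundled synthetic-data generator
    produces a genome, annotations, sRNA reads and spliced RNA-seq
    alignments with known truth against which every stage is validated.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    BiocGenerics,
    GenomicAlignments,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
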