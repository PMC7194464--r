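# phasilens

Inference tools for miRNA-directed post-transcriptional silencing from
small-RNA sequencing data, written for the common situation in non-model
plants where a miRNA is too scarce to see directly but its catalytic
footprint is not: an sRNA-guided slice through a target mRNA, followed by
DICER processing of the amplified double-stranded RNA into 21-nt
small-interfering RNAs laid down *in register* downstream of the cut.

`phasilens` implements the full chain of evidence as reusable, tested
components:

1. **Preprocessing** — 3' adapter trimming, length filtering (default
   ≥ 18 nt), read collapsing (`>tK_xN` collapsed-FASTA dialect) and
   reads-per-million normalisation.
2. **MIRNA annotation** — mapping with at most one substitution on either
   strand, fractional-coverage clustering (`mincov` 15), window folding
   (≤ `foldsize` 340 nt) by base-pair maximisation (Nussinov DP with G:U
   wobble and a stacking tie-break), and duplex criteria: a dominant
   mature read (≥ 50 % of window abundance), a star read forming a duplex
   with ≤ 5 unpaired mature bases and exact 2-nt 3' overhangs on both
   strands, and locus precision ≥ 0.75.
3. **Slice-site detection** — Allen-style complementarity penalty
   (match 0, G:U 0.5, mismatch 1, positions 2–13 doubled), a
   pseudo-degradome T-plot of sense-strand sRNA 5' ends per transcript
   position, cleavage categories 0–4, and the nt-10 rule: a site spanning
   transcript `s..e` is sliced at `e − 9`, the base paired to miRNA
   nucleotide 10.
4. **Phasing** — register assignment in 21-nt cycles anchored at the
   slice site, with the 2-nt 3' overhang rule for antisense reads
   (in phase iff `(end − s) mod 21 == 18`), and a phase score
   `(k − 2) · ln(1 + 10 P / (1 + U))` over a 10-cycle window (k = occupied
   cycles, P/U = in-/out-of-phase abundance, zero below k = 3).
5. **Tails** — decomposition of each read into a genome-templated prefix
   plus non-templated tail; classes `templated`, `mono_U`, `other_tail`,
   `ambiguous` (a templated 3' T is indistinguishable from a U tail).
6. **Quantification** — locus counts (leftmost-base rule) and RPKM from
   SAM, splice-junction extraction from `N` CIGAR operations, s.e.m.,
   t-based confidence intervals and the two-sided paired t-test.
7. **ORF comparison** — codon-by-codon diff of two equal-length CDS
   (silent / missense / nonsense) and in-frame trinucleotide-repeat
   counting.

A bundled synthetic-data generator (`build_truth_set`,
`simulate_srna_library`, `simulate_rnaseq_alignments`) produces a toy
genome carrying one MIRNA hairpin, one three-exon target gene with a
near-complementary site, phased siRNAs with the correct duplex geometry,
a mono-uridylated 22-nt miRNA variant (default probability 0.93) and
background noise — every stage of the pipeline is validated against this
known truth.

## Worked example

```r
library(phasilens)
summary <- run_all(default_config(), "demo_run")   # seed 42, noise on
str(summary)
```

prints (line noise removed):

```
$ n_reads_raw            : int 570
$ n_reads_collapsed      : int 220
$ n_mirna_loci           : int 1
$ mirna_mature_seq       : chr "TCGGACTGTTAGCATCCTGAA"
$ n_slice_sites          : int 1
$ slice_position         : int 112
$ slice_category         : int 0
$ phase_anchor           : int 112
$ phase_score            : num 16.8
$ phase_k                : int 8
$ phase_verdict          : chr "phased"
$ tail_frac_mono_U_22    : num 0.95
$ tail_frac_templated_21 : num 1
$ n_junctions            : int 2
$ junction_lengths       : chr "1113,1340"
```

Reading: the annotator accepted exactly one MIRNA hairpin and recovered
its mature sequence; scanning the target transcript with that sequence
found one site whose nt-10 position (112) is the transcript-wide maximum
of sRNA 5' ends (category 0); the phase score at that anchor is 16.8 with
all 8 phased cycles occupied, so the transcript is called a phasiRNA
producer; 95 % of the 22-nt mature-miRNA reads carry a non-templated 3' U
(the generative probability was 0.93; the remainder is the binomial
draw); and the spliced RNA-seq alignments support the two annotated
introns of 1113 and 1340 nt. Per-stage tables are under `demo_run/`, with
`summary.tsv` and `manifest.tsv` at the top.

The command-line wrapper (installed under `inst/scripts/`) exposes the
same pipeline:

```sh
Rscript inst/scripts/phasilens run-all --out demo_run
Rscript inst/scripts/phasilens stats --test paired-t --x 1,2,3 --y 2,4,6
# t=-3.4641 df=2 p=0.0741799
```

## Documentation

The methods vignette (`vignettes/phasilens-methods.Rmd`) describes the
model and its assumptions, every tunable parameter with its default and
rationale, what the synthetic generator does and does not emulate, and
the package's numerical choices and limitations.
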