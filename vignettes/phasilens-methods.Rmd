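---
title: "phasilens: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phasilens: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasilens)
```

# The inference problem

Some plant miRNAs are expressed at the edge of detectability — a fraction
of a read per million — yet are catalytically consequential: one
ARGONAUTE-loaded copy slices its target mRNA between the bases paired to
miRNA nucleotides 10 and 11, RNA-dependent RNA polymerase amplifies the
remnant, and DICER dices the duplex into 21-nt secondary siRNAs
(phasiRNAs) whose 5' ends fall at fixed 21-nt intervals downstream of the
cut. The cut therefore "sets the register", and the register is visible
in ordinary sRNA libraries even when the trigger miRNA barely is.
`phasilens` packages this inference chain: annotate the MIRNA locus from
sRNA clusters, score target complementarity, locate the slice from a
pseudo-degradome of sRNA 5' ends, quantify the 21-nt phasing, classify
3'-uridylated miRNA variants, and support the flanking expression and
coding-sequence comparisons.

All coordinates are 1-based inclusive throughout, following the
R/Bioconductor container conventions (IRanges, GRanges, Biostrings);
GFF3 and SAM are 1-based formats, so nothing is translated at the
boundaries.

# Model components and parameters

## Preprocessing

Adapter trimming removes everything from the leftmost exact occurrence of
the full 3' adapter; when the full adapter is absent the longest adapter
*prefix* of at least 8 nt anchored at the read 3' end is removed. This
reproduces the dominant behaviour of the classic clipper tools without
their mismatch heuristics; with error-free synthetic reads the two
behaviours coincide, which is why exact matching was chosen. The insert
length cutoff defaults to 18 nt. Reads-per-million is
`count / library_total * 1e6`; the collapsed-FASTA dialect writes
headers `>tK_xN` (K = abundance rank, N = count), the input convention of
downstream phasing tools.

## MIRNA annotation

* `max_mismatch = 1` — mapping allows one substitution on either strand,
  no indels. Multi-mapping reads contribute `1 / n_hits` to coverage so a
  two-locus read is not counted twice.
* `mincov = 15`, `foldsize = 340` — cluster peak-coverage threshold and
  the cap on the folded window, both fixed by the upstream protocol.
  The window is centred on the cluster; the hairpin's two arms form two
  separate read clusters (the loop is uncovered), so accepted candidates
  are deduplicated on the mature-arm interval.
* Folding is **base-pair maximisation**, not thermodynamic MFE: a
  Nussinov dynamic program over Watson–Crick plus G:U pairs with hairpin
  loops ≥ 3 nt. This is a deliberate deviation from RNAfold-class tools,
  made to avoid an external folding dependency; on a clean hairpin it
  yields the same accept/reject decision. Maximum-cardinality structures
  are massively degenerate, so ties are resolved by **maximising the
  number of stacked pairs** (pairs whose neighbour `(i+1, j-1)` is also
  paired) — a discrete surrogate for stacking energy. With a naive
  tie-break the DP happily returns an equal-cardinality scattering of
  mini-helices in which the mature:star duplex is invisible; the stacking
  objective makes the long duplex the unique optimum on hairpin windows.
  Remaining ties fall deterministically to the smallest admissible
  partner, preferring a stacked continuation.
* Duplex criteria: mature dominance ≥ 0.5 of window abundance (the
  mature species pools 3'-length variants sharing its 5' end, standard
  registry practice — otherwise a locus's own tailed variant would count
  against it), a same-strand non-overlapping star whose duplex with the
  mature read leaves ≤ 5 mature bases unpaired with exact 2-nt 3'
  overhangs on both strands, and precision (mature + star) / window
  ≥ 0.75. Only `mincov` and `foldsize` are protocol-fixed; the other
  thresholds follow published MIRNA-annotation practice and are declared,
  not claimed identical to any specific annotator version.

## Slice-site detection

The duplex penalty is Allen-style: match 0, G:U wobble 0.5, mismatch 1,
costs doubled at miRNA positions 2–13 (the pairing core). Version 1
forbids bulges, so candidate sites are fixed-length windows; the default
acceptance cutoff is `penalty_max = 7`, common plant-target practice
(the protocol itself prints no cutoff). The pseudo-degradome T-plot
counts **sense-strand** read 5' ends only: slice remnants are sense
fragments, and antisense reads carry phasing, not cleavage, information.
Cleavage categories follow the degradome convention: 4 = singleton read;
0 = unique transcript-wide maximum; 1 = shared maximum; 2 = above the
median of occupied positions; 3 = at or below it (ties at the median
resolve downward, i.e. to 3); a zero count is "no cleavage evidence",
not a category. The slice position of a site spanning `s..e` is `e − 9`
— antiparallel pairing puts miRNA nucleotide 10 opposite that base. All
read lengths 18–26 nt count as pseudo-degradome evidence (whether the
original protocol restricted to 20–22 is not recorded; counting all is
the weaker assumption).

## Phasing

Plus-strand reads are in phase iff `(start − s) mod 21 == 0`. DICER
leaves 2-nt 3' overhangs, so the antisense partner of sense cycle k spans
`s+21k−2 .. s+21k+18`; minus-strand reads are therefore in phase iff
`(end − s) mod 21 == 18` (= period − 3). The phase score over a 10-cycle
window anchored at `s` is

$$\mathrm{score} = (k-2)\,\ln\!\Big(1 + \frac{10\,P}{1+U}\Big),\qquad k \ge 3,$$

with `k` the number of occupied phase cycles (both strands pooled), `P`
the in-phase and `U` the out-of-phase abundance; below `k = 3` the score
is 0. This is the Howell-style convention; the phasing tool used by the
original protocol scores differently and prints no formula, so the
score here is declared and tested against its own definition. Only
20–22-nt reads (DCL-sized products) count toward `P`, `U` and `k`;
other lengths still receive register flags. Anchors are searched at
detected slice sites (plus any user-supplied positions), not
genome-wide — the trigger-first logic of the analysis. The verdict
threshold defaults to `score_min = 4` (≈ one clean cycle above the gate:
three occupied cycles of modest abundance with little background already
exceed it, e.g. `ln 101 ≈ 4.6`).

## Tails

A read is decomposed at its anchor into the longest genome-matching
prefix plus the remainder. `mono_U`: exactly the final base mismatches
and is a T. `ambiguous`: the read matches the genome entirely *and* ends
in T — a templated T cannot be distinguished from a coincidental
non-templated U, and the class is excluded from both numerator and
denominator of the reported fractions (the conservative reading of
"appear to have undergone" uridylation). Multi-base tails are
`other_tail` with the tail string preserved; modelling tail-length
distributions is out of scope. Prefixes shorter than 18 templated nt are
`unanchored`.

## Quantification and statistics

Locus assignment uses the leftmost aligned base (deterministic,
order-independent); RPKM is `count / (locus_kb × mapped_millions)` with
single-end semantics. Junctions come from `N` CIGAR operations with
donor = first intronic base and acceptor = first base after the intron
(half-open, so skip length = acceptor − donor). `sem_ci` and
`paired_t_test` implement the textbook formulas (`sd` with n−1,
two-sided p); zero-variance differences follow an explicit degenerate
contract (p = 1 at zero mean difference, else p = 0). The stage-wise
pairing used by the original figure legend is ambiguous at n = 1 per
stage, so the package exposes the generic paired test and leaves the
pairing choice to the caller.

## ORF comparison

Codon-by-codon diff of two equal-length, in-frame CDS under the standard
nuclear genetic code, residues numbered from the initiator methionine;
classes silent / missense / nonsense. Frameshifted inputs are rejected:
restoring a frame (as when an assembly lacks bases that RNA-seq
shows are transcribed) is manual curation, not an algorithm, and
deliberately out of scope. `count_codon_repeat` measures
the maximal run of in-frame motif copies from a given residue, the
operation behind "six instead of seven" GGC comparisons.

# The synthetic truth set

The generator builds one chromosome (~4.3 kb) containing:

* a **MIRNA hairpin**: a fixed arbitrary 21-nt mature sequence (not a
  real miR828 — the real sequence is not modelled), a 15-nt loop, and a
  star arm equal to the reverse complement of mature positions 1–19 plus
  two overhang bases, giving a perfect 19-bp duplex with exact 2-nt 3'
  overhangs. The hairpin sits in a 170-nt A/C-only flank on each side
  and both overhangs are A/A, so no base outside the duplex can extend
  it: the maximum base-pairing structure of the full fold window is
  exactly the duplex, making the annotation test deterministic.
* a **three-exon target gene** (exons 400/150/150 nt, introns 1113 and
  1340 nt, the intron lengths annotated for the F153 pineapple
  target). Exon 1 carries the target site at transcript positions
  101–121: the reverse complement of the mature sequence with one G:U
  wobble opposite miRNA position 15 (penalty 0.5), so the slice position
  is 112.
* **reads**: 120 copies of the 21-nt mature, 40 of the 22-nt species —
  each non-templated mono-U (`mature + T`, genome has C) with
  probability `p_mono_U = 0.93`, the fraction estimated in pineapple
  leaf libraries, else
  the templated 22-mer — 20 star copies; 8 phased cycles of sense and
  antisense 21-mers with the duplex-overhang geometry (10 + 10 per cycle,
  the first sense position boosted by 30 to make the slice remnant the
  T-plot maximum, as the documented "red dot" species is in real data);
  and 200 background reads drawn uniformly from the genome at 18–26 nt,
  the simplest null occupying the analysed size range.
* **RNA-seq**: 100-nt single-end reads uniform along the transcript
  (junction reads carry the intron-length `N` skips) plus contiguous
  reads over the precursor region; constant quality, no sequencing
  errors.

Counts are exact (`depth` acts as a pure multiplier); the only
stochastic elements are read placement, strand flags, the mono-U
binomial draw and output shuffling, each drawn from a stream seeded by
`(global seed, stage-name hash)` so stages are independently
reproducible and byte-identical under a fixed seed.

One deliberate departure from the motivating observations: the 21- and 22-nt
mature classes are *not* equally abundant here (120 vs 40). The narrative
ratio is not a tested constant, and an equal split would leave the most
abundant single read below the 50 % dominance criterion on its own
locus — the generator states a world in which the annotation criteria
are satisfiable, and says so here rather than weakening the criteria.

What a green test establishes — and does not. The generator has no
sequencing errors, no replicate structure beyond independent seeds, no
quality-score realism, no bulged target sites, and background noise is
uniform rather than structured (no degradation ladders, no rRNA/tRNA
fragments). Passing tests therefore demonstrate correctness of the
*inference machinery* on data satisfying its assumptions, not robustness
to every artefact of real libraries.

# Numerical and degenerate-input choices

* Folding tie-breaks are fully specified (stacking count, then smallest
  partner) so structures are reproducible across platforms; the fold of
  a window longer than `foldsize` is an error, not a truncation.
* `categorize_position` on a zero count raises "no cleavage evidence"
  rather than inventing a category; the category partition is tested
  property-style against an independent re-derivation.
* Register arithmetic uses R's non-negative `%%`, so reads upstream of
  the anchor get well-defined registers; `phase_score` at anchors `s`
  and `s + 21` agrees on reads inside both windows (tested).
* An empty preprocessed library propagates as empty tables with a
  warning, exit 0 — an empty result is an answer, not a crash.
* `rpm_normalize` refuses a library total smaller than the summed
  counts; `simulate_*` refuse non-positive depth; config files refuse
  out-of-range `p_mono_U`.

# Known limitations

* No bulged target alignment (fixed-length windows); genome-wide
  de-novo PHAS scanning without anchors is out of scope, as is 24-nt
  phasing.
* Base-pair maximisation is not a thermodynamic model; hairpins whose
  acceptance hinges on energy differences rather than pair counts may be
  mis-evaluated. The criteria here are declared, versionless, and tested
  against the bundled truth — not claimed identical to any published
  annotator's internals.
* True degradome (PARE) parsing is not implemented; the pseudo-degradome
  substitutes sRNA 5' ends for degradome reads, on the grounds that
  sliced mRNAs feeding amplified diced dsRNA are themselves manifest in
  sRNA libraries — valid exactly where that amplification occurs.
* The paired t-test degenerate contract (p ∈ {0, 1} at zero variance) is
  a stated convention, not an inferential claim.
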