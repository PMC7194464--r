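# Classification of 3'-tailed (non-templated) sRNA species, chiefly
# mono-uridylation: each read is decomposed into its longest
# genome-templated prefix at an anchor alignment plus a (possibly empty)
# non-templated tail.

#' Classify the 3' tail of one read at an anchor alignment
#'
#' The read's 5' end is anchored at `start` (plus strand) or `end` (minus
#' strand); bases are compared to the genome outward from the anchor.
#' Classes: `templated` (full match, final base not T), `ambiguous` (full
#' match ending in T - a templated T is indistinguishable from a
#' coincidental U tail), `mono_U` (exactly the final base mismatches and is
#' T), `other_tail` (any other mismatching suffix). A templated prefix
#' shorter than `min_prefix` is rejected as `unanchored`.
#'
#' @param read read sequence.
#' @param genome named character vector or `DNAStringSet`.
#' @param seqid,start,strand anchor: chromosome, 1-based position of the
#'   read's 5' end on the genome (`start` is the leftmost genomic base of
#'   the read for "+", and for "-" the read's 5' end sits at
#'   `start + nchar(read) - 1`).
#' @param min_prefix minimum templated prefix (default 18).
#' @return list (class, templated_prefix_len, tail, seqid, start, strand).
#' @export
classify_tail <- function(read, genome, seqid, start, strand = "+",
                          min_prefix = 18L) {
  gset <- as_genome(genome)
  chrom <- as.character(gset[[seqid]])
  n <- nchar(read)
  gseq <- substr(chrom, start, start + n - 1L)
  if (strand == "-") gseq <- revcomp(gseq)
  if (nchar(gseq) < n) stop("anchor runs off the chromosome", call. = FALSE)
  rb <- strsplit(read, "")[[1]]
  gb <- strsplit(gseq, "")[[1]]
  match <- rb == gb
  prefix_len <- if (all(match)) n else which(!match)[1] - 1L
  if (prefix_len < min_prefix) {
    return(list(class = "unanchored", templated_prefix_len = prefix_len,
                tail = substr(read, prefix_len + 1L, n),
                seqid = seqid, start = start, strand = strand))
  }
  tail <- substr(read, prefix_len + 1L, n)
  cls <- if (prefix_len == n) {
    if (rb[n] == "T") "ambiguous" else "templated"
  } else if (n - prefix_len == 1L && tail == "T") {
    "mono_U"
  } else {
    "other_tail"
  }
  list(class = cls, templated_prefix_len = prefix_len, tail = tail,
       seqid = seqid, start = start, strand = strand)
}

#' Classify tails for a collapsed read set against a genome
#'
#' Each read is anchored by its best genome alignment (fewest mismatches,
#' then leftmost) under a `max_mismatch` substitution allowance and
#' classified with [classify_tail()]. Reads with no alignment are
#' `unanchored`.
#'
#' @param reads collapsed reads data.frame (`sequence`, `count`).
#' @param genome named character vector or `DNAStringSet`.
#' @param max_mismatch mapping allowance (default 1).
#' @param min_prefix minimum templated prefix (default 18).
#' @return data.frame (sequence, length, count, class,
#'   templated_prefix_len, tail).
#' @export
call_tails <- function(reads, genome, max_mismatch = 1L, min_prefix = 18L) {
  aln <- map_reads(reads, genome, max_mismatch)
  out <- lapply(seq_len(nrow(reads)), function(i) {
    rs <- reads$sequence[i]
    a <- aln[aln$sequence == rs, , drop = FALSE]
    if (nrow(a) == 0L) {
      return(data.frame(sequence = rs, length = nchar(rs),
                        count = reads$count[i], class = "unanchored",
                        templated_prefix_len = 0L, tail = "",
                        anchor_seqid = NA_character_, anchor_start = NA_integer_,
                        anchor_strand = NA_character_, stringsAsFactors = FALSE))
    }
    a <- a[order(a$mismatches, a$seqid, a$start), , drop = FALSE]
    tc <- classify_tail(rs, genome, a$seqid[1], a$start[1], a$strand[1],
                        min_prefix)
    data.frame(sequence = rs, length = nchar(rs), count = reads$count[i],
               class = tc$class, templated_prefix_len = tc$templated_prefix_len,
               tail = tc$tail, anchor_seqid = a$seqid[1],
               anchor_start = a$start[1], anchor_strand = a$strand[1],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Abundance-weighted tail fractions by read-length class
#'
#' For each length class: fractions of templated / mono_U / other_tail
#' abundance, with ambiguous calls reported separately and excluded from
#' both numerator and denominator (a templated 3' T cannot be told apart
#' from a coincidental U tail); plus the class's share of total abundance.
#' Fractions of an empty class are `NA`, not 0.
#'
#' @param calls data.frame from [call_tails()].
#' @param length_classes integer vector of lengths to report (default: all
#'   observed lengths).
#' @return data.frame (length, abundance, share, frac_templated,
#'   frac_mono_U, frac_other_tail, frac_ambiguous).
#' @export
tail_fraction_report <- function(calls,
                                 length_classes = sort(unique(calls$length))) {
  total <- sum(calls$count)
  rows <- lapply(length_classes, function(L) {
    cl <- calls[calls$length == L & calls$class != "unanchored", , drop = FALSE]
    ab <- sum(cl$count)
    amb <- sum(cl$count[cl$class == "ambiguous"])
    denom <- ab - amb
    frac <- function(k) if (denom > 0) sum(cl$count[cl$class == k]) / denom
                        else NA_real_
    data.frame(length = L, abundance = ab,
               share = if (total > 0) ab / total else NA_real_,
               frac_templated = frac("templated"),
               frac_mono_U = frac("mono_U"),
               frac_other_tail = frac("other_tail"),
               frac_ambiguous = if (ab > 0) amb / ab else NA_real_)
  })
  do.call(rbind, rows)
}
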