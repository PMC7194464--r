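# MIRNA locus annotation from genome-mapped sRNA clusters: short-read
# mapping (<= 1 substitution, both strands), fractional coverage clustering,
# window folding and duplex-criteria evaluation (dominant mature read, star
# read with 2-nt 3' overhangs, locus precision).

#' Default MIRNA-annotation thresholds
#'
#' Dominance and precision thresholds follow published MIRNA-annotation
#' practice; only `mincov` and `foldsize` are fixed by the upstream
#' protocol (15 and 340).
#'
#' @return named list (dominance, precision_min, max_unpaired, overhang).
#' @export
mirna_default_thresholds <- function() {
  list(dominance = 0.5, precision_min = 0.75, max_unpaired = 5L, overhang = 2L)
}

as_genome <- function(genome) {
  if (is(genome, "DNAStringSet")) return(genome)
  if (is.character(genome)) {
    if (is.null(names(genome))) stop("genome must be named", call. = FALSE)
    return(Biostrings::DNAStringSet(genome))
  }
  stop("genome must be a named character vector or DNAStringSet", call. = FALSE)
}

#' Map collapsed reads to a genome allowing substitutions
#'
#' Reports every alignment of every read with at most `max_mismatch`
#' substitutions (no indels), on both strands; minus-strand alignments are
#' reported on the genomic interval covered by the reverse complement.
#' Reads containing N are excluded from mapping.
#'
#' @param reads data.frame with columns `sequence` and `count` (a bare
#'   character vector is taken with unit counts).
#' @param genome named character vector or `DNAStringSet`.
#' @param max_mismatch 0 or 1.
#' @return data.frame (sequence, count, seqid, start, end, strand,
#'   mismatches, n_hits).
#' @export
map_reads <- function(reads, genome, max_mismatch = 1L) {
  if (!max_mismatch %in% c(0L, 1L)) {
    stop("max_mismatch must be 0 or 1", call. = FALSE)
  }
  gset <- as_genome(genome)
  if (length(gset) == 0L || sum(Biostrings::width(gset)) == 0L) {
    stop("empty genome", call. = FALSE)
  }
  if (is.character(reads)) {
    reads <- data.frame(sequence = reads, count = 1L, stringsAsFactors = FALSE)
  }
  reads <- reads[!grepl("N", reads$sequence, fixed = TRUE), , drop = FALSE]
  hits <- list()
  for (r in seq_len(nrow(reads))) {
    rs <- reads$sequence[r]
    pat_fwd <- Biostrings::DNAString(rs)
    pat_rev <- Biostrings::reverseComplement(pat_fwd)
    for (ci in seq_along(gset)) {
      chrom <- gset[[ci]]
      for (std in c("+", "-")) {
        pat <- if (std == "+") pat_fwd else pat_rev
        m <- Biostrings::matchPattern(pat, chrom, max.mismatch = max_mismatch,
                                      with.indels = FALSE)
        if (length(m) == 0L) next
        mm <- Biostrings::neditStartingAt(pat, chrom, starting.at = IRanges::start(m))
        hits[[length(hits) + 1L]] <- data.frame(
          sequence = rs, count = reads$count[r],
          seqid = names(gset)[ci],
          start = IRanges::start(m), end = IRanges::end(m),
          strand = std, mismatches = as.integer(mm),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(sequence = character(0), count = integer(0),
                      seqid = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      mismatches = integer(0), n_hits = integer(0),
                      stringsAsFactors = FALSE))
  }
  aln <- do.call(rbind, hits)
  nh <- table(aln$sequence)
  aln$n_hits <- as.integer(nh[aln$sequence])
  rownames(aln) <- NULL
  aln
}

#' Cluster alignments by read coverage
#'
#' Per-base coverage sums `count / n_hits` (multi-mapping reads count
#' fractionally) over both strands. Clusters are maximal runs of covered
#' bases whose peak coverage reaches `mincov`; runs are separated by at
#' least one uncovered base.
#'
#' @param aln alignment data.frame from [map_reads()].
#' @param seqlens named integer vector of chromosome lengths.
#' @param mincov minimum peak coverage (default 15).
#' @return data.frame (seqid, start, end, max_cov).
#' @export
cluster_by_coverage <- function(aln, seqlens, mincov = 15) {
  if (mincov < 1) stop("mincov must be >= 1", call. = FALSE)
  out <- list()
  for (sq in names(seqlens)) {
    a <- aln[aln$seqid == sq, , drop = FALSE]
    if (nrow(a) == 0L) next
    cov <- as.numeric(IRanges::coverage(
      IRanges::IRanges(a$start, a$end),
      weight = a$count / a$n_hits, width = seqlens[[sq]]))
    r <- rle(cov > 0)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      peak <- max(cov[starts[k]:ends[k]])
      if (peak >= mincov) {
        out[[length(out) + 1L]] <- data.frame(
          seqid = sq, start = starts[k], end = ends[k], max_cov = peak,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(seqid = character(0), start = integer(0),
                      end = integer(0), max_cov = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# 5' end of an alignment row in genomic coordinates.
five_prime_end <- function(aln) ifelse(aln$strand == "+", aln$start, aln$end)

#' Evaluate one folded window against MIRNA duplex criteria
#'
#' Accepts the window iff (a) one dominant read (the mature species, pooled
#' over 3'-length variants sharing its 5' end and strand) carries at least
#' `dominance` of the window abundance; (b) a non-overlapping same-strand
#' star read forms a duplex with the mature read leaving at most
#' `max_unpaired` mature bases unpaired and exactly `overhang` nt 3'
#' overhangs on both strands; and (c) precision
#' (mature + star) / (all window reads) reaches `precision_min`.
#'
#' @param window list or one-row data.frame with seqid, start, end.
#' @param aln alignments from [map_reads()] (any subset covering the window).
#' @param pairing pairing data.frame from [fold_window()] on the window
#'   sequence, in local coordinates of `fold_strand`.
#' @param fold_strand strand on which the window was folded ("+" or "-").
#' @param thresholds list from [mirna_default_thresholds()].
#' @return list (accept, reason, mature, star, precision, overhangs).
#' @export
evaluate_hairpin <- function(window, aln, pairing, fold_strand = "+",
                             thresholds = mirna_default_thresholds()) {
  w <- as.list(window)
  win <- aln[aln$seqid == w$seqid & aln$start >= w$start & aln$end <= w$end, ,
             drop = FALSE]
  if (nrow(win) == 0L) {
    return(list(accept = FALSE, reason = "no_reads"))
  }
  total <- sum(win$count)
  win <- win[order(-win$count, win$start, win$sequence), , drop = FALSE]
  dom <- win[1L, ]
  fp <- five_prime_end(win)
  mature_rows <- win$strand == dom$strand & fp == five_prime_end(dom)
  mature_abund <- sum(win$count[mature_rows])
  if (mature_abund / total < thresholds$dominance) {
    return(list(accept = FALSE, reason = "no_dominant_read", total = total))
  }

  # local (fold-strand 5'->3') coordinates inside the window
  loc <- function(gs, ge) {
    if (fold_strand == "+") c(gs - w$start + 1L, ge - w$start + 1L)
    else c(w$end - ge + 1L, w$end - gs + 1L)
  }
  m_loc <- loc(dom$start, dom$end)
  mat_len <- dom$end - dom$start + 1L

  cand <- win[win$strand == dom$strand &
              (win$end < dom$start | win$start > dom$end), , drop = FALSE]
  star <- NULL
  star_overhangs <- NULL
  if (nrow(cand)) {
    for (ci in seq_len(nrow(cand))) {
      s_loc <- loc(cand$start[ci], cand$end[ci])
      in_m <- pairing$i >= m_loc[1] & pairing$i <= m_loc[2] &
              pairing$j >= s_loc[1] & pairing$j <= s_loc[2]
      in_m2 <- pairing$j >= m_loc[1] & pairing$j <= m_loc[2] &
               pairing$i >= s_loc[1] & pairing$i <= s_loc[2]
      m_paired <- c(pairing$i[in_m], pairing$j[in_m2])
      s_paired <- c(pairing$j[in_m], pairing$i[in_m2])
      if (length(m_paired) == 0L) next
      unpaired_m <- mat_len - length(unique(m_paired))
      oh_m <- m_loc[2] - max(m_paired)
      oh_s <- s_loc[2] - max(s_paired)
      if (unpaired_m <= thresholds$max_unpaired &&
          oh_m == thresholds$overhang && oh_s == thresholds$overhang) {
        star <- cand[ci, ]
        star_overhangs <- c(mature = oh_m, star = oh_s)
        break  # cand is ordered by abundance; first hit is the best star
      }
    }
  }
  if (is.null(star)) {
    return(list(accept = FALSE, reason = "no_star", total = total))
  }
  star_rows <- win$strand == star$strand & fp == five_prime_end(star)
  star_abund <- sum(win$count[star_rows])
  precision <- (mature_abund + star_abund) / total
  if (precision < thresholds$precision_min) {
    return(list(accept = FALSE, reason = "low_precision",
                precision = precision, total = total))
  }
  list(accept = TRUE, reason = "ok",
       mature = dom, star = star, mature_abund = mature_abund,
       star_abund = star_abund, precision = precision,
       overhangs = star_overhangs, total = total)
}

#' Annotate MIRNA loci from collapsed reads and a genome
#'
#' Maps reads, clusters coverage, folds a window of at most `foldsize` nt
#' centred on each cluster (on the strand of the cluster's dominant read)
#' and evaluates the duplex criteria. Accepted candidates arising from both
#' the mature-arm and star-arm clusters of the same hairpin are
#' deduplicated.
#'
#' @param reads collapsed reads data.frame (`sequence`, `count`).
#' @param genome named character vector or `DNAStringSet`.
#' @param mincov minimum cluster peak coverage (default 15).
#' @param foldsize maximum fold-window length (default 340).
#' @param max_mismatch mapping mismatch allowance (default 1).
#' @param min_loop minimum hairpin loop (default 3).
#' @param thresholds duplex criteria, see [mirna_default_thresholds()].
#' @return list with `report` (one row per evaluated cluster), `accepted`
#'   (deduplicated accepted loci), `alignments`, `clusters`.
#' @export
annotate_mirna <- function(reads, genome, mincov = 15, foldsize = 340L,
                           max_mismatch = 1L, min_loop = 3L,
                           thresholds = mirna_default_thresholds()) {
  gset <- as_genome(genome)
  seqlens <- stats::setNames(Biostrings::width(gset), names(gset))
  aln <- map_reads(reads, gset, max_mismatch)
  clusters <- cluster_by_coverage(aln, seqlens, mincov)
  report <- list()
  accepted <- list()
  for (k in seq_len(nrow(clusters))) {
    cl <- clusters[k, ]
    center <- (cl$start + cl$end) %/% 2L
    half <- foldsize %/% 2L
    wstart <- max(1L, center - half + 1L)
    wend <- min(seqlens[[cl$seqid]], wstart + foldsize - 1L)
    win <- list(seqid = cl$seqid, start = wstart, end = wend)
    wa <- aln[aln$seqid == cl$seqid & aln$start >= wstart & aln$end <= wend, ,
              drop = FALSE]
    if (nrow(wa) == 0L) next
    dom_strand <- wa$strand[which.max(wa$count)]
    wseq <- substr(as.character(gset[[cl$seqid]]), wstart, wend)
    if (dom_strand == "-") wseq <- revcomp(wseq)
    pairing <- fold_window(wseq, min_loop = min_loop, foldsize = foldsize)
    ev <- evaluate_hairpin(win, wa, pairing, fold_strand = dom_strand,
                           thresholds = thresholds)
    row <- data.frame(
      seqid = cl$seqid, cluster_start = cl$start, cluster_end = cl$end,
      window_start = wstart, window_end = wend,
      verdict = if (isTRUE(ev$accept)) "accept" else "reject",
      reason = ev$reason,
      mature_seq = if (isTRUE(ev$accept)) ev$mature$sequence else NA_character_,
      star_seq = if (isTRUE(ev$accept)) ev$star$sequence else NA_character_,
      mature_start = if (isTRUE(ev$accept)) ev$mature$start else NA_integer_,
      mature_end = if (isTRUE(ev$accept)) ev$mature$end else NA_integer_,
      star_start = if (isTRUE(ev$accept)) ev$star$start else NA_integer_,
      star_end = if (isTRUE(ev$accept)) ev$star$end else NA_integer_,
      strand = if (isTRUE(ev$accept)) ev$mature$strand else NA_character_,
      precision = if (!is.null(ev$precision)) ev$precision else NA_real_,
      stringsAsFactors = FALSE)
    report[[length(report) + 1L]] <- row
    if (isTRUE(ev$accept)) accepted[[length(accepted) + 1L]] <- row
  }
  report <- if (length(report)) do.call(rbind, report) else
    data.frame(seqid = character(0), verdict = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  accepted <- if (length(accepted)) do.call(rbind, accepted) else report[0, ]
  if (nrow(accepted)) {
    key <- paste(accepted$seqid, accepted$mature_start, accepted$mature_end,
                 accepted$strand)
    accepted <- accepted[!duplicated(key), , drop = FALSE]
  }
  list(report = report, accepted = accepted, alignments = aln,
       clusters = clusters)
}

#' Export accepted MIRNA loci as GFF3
#'
#' @param accepted `accepted` table from [annotate_mirna()].
#' @param path output GFF3 path.
#' @return invisibly, the path.
#' @export
write_mirna_gff <- function(accepted, path) {
  if (nrow(accepted) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  n <- nrow(accepted)
  gr <- GenomicRanges::GRanges(
    seqnames = rep(accepted$seqid, each = 3L),
    ranges = IRanges::IRanges(
      start = as.vector(rbind(pmin(accepted$mature_start, accepted$star_start),
                              accepted$mature_start, accepted$star_start)),
      end = as.vector(rbind(pmax(accepted$mature_end, accepted$star_end),
                            accepted$mature_end, accepted$star_end))),
    strand = rep(accepted$strand, each = 3L),
    type = rep(c("MIRNA_primary_transcript", "miRNA", "miRNA_star"), n),
    ID = as.vector(rbind(sprintf("MIRNA%d", seq_len(n)),
                         sprintf("MIRNA%d_mature", seq_len(n)),
                         sprintf("MIRNA%d_star", seq_len(n)))),
    Parent = as.vector(rbind(NA, sprintf("MIRNA%d", seq_len(n)),
                             sprintf("MIRNA%d", seq_len(n)))))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
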