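# Locus-level expression from SAM alignments, splice-junction extraction,
# and the summary statistics used downstream (s.e.m., confidence interval,
# paired t-test).

#' Read a SAM file into a record table
#'
#' Parses through samtools (Rsamtools), keeping primary alignments only
#' (secondary 0x100 and supplementary 0x800 records are dropped; unmapped
#' records are dropped too).
#'
#' @param path SAM (or BAM) file path.
#' @return data.frame (qname, flag, rname, pos, mapq, cigar).
#' @export
read_sam <- function(path) {
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- tryCatch(
      Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                       indexDestination = FALSE),
      error = function(e) stop(sprintf("malformed SAM '%s': %s", path,
                                       conditionMessage(e)), call. = FALSE))
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar"),
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isUnmappedQuery = FALSE))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  data.frame(qname = x$qname, flag = x$flag, rname = as.character(x$rname),
             pos = x$pos, mapq = x$mapq, cigar = x$cigar,
             stringsAsFactors = FALSE)
}

#' Count primary alignments per locus and compute RPKM
#'
#' A read is assigned to a locus iff its leftmost aligned base lies within
#' the locus interval (deterministic leftmost-base rule).
#' `rpkm = count / (locus_kb * total_mapped_millions)`.
#'
#' @param sam record table from [read_sam()] (primary alignments).
#' @param loci data.frame (locus, seqid, start, end).
#' @param total_mapped denominator for RPKM; defaults to `nrow(sam)`.
#' @return data.frame (locus, seqid, start, end, count, rpkm).
#' @export
count_locus_reads <- function(sam, loci, total_mapped = nrow(sam)) {
  counts <- vapply(seq_len(nrow(loci)), function(i) {
    sum(sam$rname == loci$seqid[i] &
        sam$pos >= loci$start[i] & sam$pos <= loci$end[i])
  }, numeric(1))
  kb <- (loci$end - loci$start + 1) / 1e3
  mill <- total_mapped / 1e6
  data.frame(locus = loci$locus, seqid = loci$seqid,
             start = loci$start, end = loci$end, count = counts,
             rpkm = if (total_mapped > 0) counts / (kb * mill) else NA_real_,
             stringsAsFactors = FALSE)
}

parse_cigar <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  if (length(ops) == 0L || paste(ops, collapse = "") != cigar) {
    stop(sprintf("invalid CIGAR '%s'", cigar), call. = FALSE)
  }
  data.frame(len = as.integer(sub("[A-Z=]$", "", ops)),
             op = sub("^\\d+", "", ops), stringsAsFactors = FALSE)
}

#' Extract splice junctions from SAM records
#'
#' Walks each CIGAR; every `N` (skip) operation yields a junction with
#' donor = first intronic base and acceptor = first base after the intron
#' (half-open, so `skip_length = acceptor - donor`). Identical junctions
#' are merged with summed read support. Order-independent.
#'
#' @param sam record table from [read_sam()].
#' @return data.frame (seqid, donor, acceptor, skip_length, supporting_reads).
#' @export
extract_junctions <- function(sam) {
  ref_consumes <- c(M = TRUE, I = FALSE, D = TRUE, N = TRUE, S = FALSE,
                    H = FALSE, P = FALSE, `=` = TRUE, X = TRUE)
  out <- list()
  for (i in seq_len(nrow(sam))) {
    cig <- parse_cigar(sam$cigar[i])
    refpos <- sam$pos[i]
    for (k in seq_len(nrow(cig))) {
      if (cig$op[k] == "N") {
        out[[length(out) + 1L]] <- data.frame(
          seqid = sam$rname[i], donor = refpos,
          acceptor = refpos + cig$len[k], stringsAsFactors = FALSE)
      }
      if (ref_consumes[[cig$op[k]]]) refpos <- refpos + cig$len[k]
    }
  }
  if (length(out) == 0L) {
    return(data.frame(seqid = character(0), donor = integer(0),
                      acceptor = integer(0), skip_length = integer(0),
                      supporting_reads = integer(0), stringsAsFactors = FALSE))
  }
  j <- do.call(rbind, out)
  agg <- stats::aggregate(list(supporting_reads = rep(1L, nrow(j))),
                          by = list(seqid = j$seqid, donor = j$donor,
                                    acceptor = j$acceptor), FUN = sum)
  agg$skip_length <- agg$acceptor - agg$donor
  agg <- agg[order(agg$seqid, agg$donor, agg$acceptor), , drop = FALSE]
  rownames(agg) <- NULL
  agg[, c("seqid", "donor", "acceptor", "skip_length", "supporting_reads")]
}

#' Mean, standard error and t-based confidence interval
#'
#' `sem = sd / sqrt(n)` (n-1 denominator in `sd`); the interval is
#' `mean +/- t(1 - alpha/2, n - 1) * sem`.
#'
#' @param values numeric vector, `n >= 2`.
#' @param confidence confidence level (default 0.95).
#' @return list (mean, sem, ci_low, ci_high, n).
#' @export
sem_ci <- function(values, confidence = 0.95) {
  n <- length(values)
  if (n < 2L) stop("need at least two values", call. = FALSE)
  m <- mean(values)
  sem <- stats::sd(values) / sqrt(n)
  tq <- stats::qt(1 - (1 - confidence) / 2, df = n - 1)
  list(mean = m, sem = sem, ci_low = m - tq * sem, ci_high = m + tq * sem,
       n = n)
}

#' Two-sided paired Student t-test
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` with `d = x - y`, `df = n - 1`,
#' two-sided p from the t distribution. Zero-variance differences follow
#' the degenerate contract: p = 1 (t = 0) if the mean difference is zero,
#' else p = 0 (t = +/-Inf).
#'
#' @param x,y paired numeric vectors of equal length, `n >= 2`.
#' @return list (t, df, p).
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 2L) stop("need at least two pairs", call. = FALSE)
  d <- x - y
  s <- stats::sd(d)
  if (s == 0) {
    if (mean(d) == 0) return(list(t = 0, df = n - 1L, p = 1))
    return(list(t = sign(mean(d)) * Inf, df = n - 1L, p = 0))
  }
  t <- mean(d) / (s / sqrt(n))
  list(t = t, df = n - 1L, p = 2 * stats::pt(-abs(t), df = n - 1L))
}
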