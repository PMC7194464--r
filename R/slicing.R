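# miRNA target-site scoring and pseudo-degradome slice-site detection.
# The pseudo-degradome substitutes sRNA-read 5' ends for true degradome
# reads: counts of sense-strand 5' ends per transcript position form a
# T-plot, each queried position gets a cleavage category (0-4), and
# candidate sites are the low-penalty complementarity windows whose nt-10
# position carries cleavage evidence.

#' Score a miRNA:target duplex (Allen-style penalty)
#'
#' Antiparallel alignment of the miRNA (5'->3') against a target window of
#' the same length (given 5'->3' in sense orientation, so miRNA position i
#' pairs target-window position `len - i + 1`). Per-position costs: match 0,
#' G:U wobble 0.5, mismatch 1.0; positions 2-13 from the miRNA 5' end are
#' doubled. No bulges: windows are fixed-length.
#'
#' @param mirna miRNA sequence (RNA or DNA alphabet).
#' @param target_window sense-strand target window, same length as `mirna`.
#' @return list (penalty, trace) where `trace` is a per-miRNA-position
#'   data.frame (position, mirna_base, target_base, kind, cost).
#' @export
score_duplex <- function(mirna, target_window) {
  mirna <- toupper(chartr("U", "T", mirna))
  target_window <- toupper(chartr("U", "T", target_window))
  n <- nchar(mirna)
  if (nchar(target_window) != n) {
    stop("target window length must equal miRNA length", call. = FALSE)
  }
  mb <- strsplit(mirna, "")[[1]]
  tb <- rev(strsplit(target_window, "")[[1]])  # antiparallel
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  kind <- ifelse(tb == comp[mb], "match",
          ifelse((mb == "G" & tb == "T") | (mb == "T" & tb == "G"),
                 "wobble", "mismatch"))
  cost <- c(match = 0, wobble = 0.5, mismatch = 1)[kind]
  core <- seq_len(n) >= 2L & seq_len(n) <= 13L
  cost[core] <- cost[core] * 2
  list(penalty = sum(cost),
       trace = data.frame(position = seq_len(n), mirna_base = mb,
                          target_base = tb, kind = kind, cost = cost,
                          stringsAsFactors = FALSE))
}

#' Build a pseudo-degradome T-plot
#'
#' Accumulates abundances of sense-strand read 5' ends per transcript
#' position; antisense alignments are excluded (they are retained for
#' phasing, not cleavage evidence).
#'
#' @param aln alignments on the transcript (data.frame with start, end,
#'   strand, count).
#' @param transcript_len transcript length.
#' @param transcript_id optional id stored on the result.
#' @return list of class `phasilens_tplot` (transcript, counts).
#' @export
build_tplot <- function(aln, transcript_len, transcript_id = NA_character_) {
  counts <- numeric(transcript_len)
  sense <- aln[aln$strand == "+", , drop = FALSE]
  if (nrow(sense)) {
    agg <- tapply(sense$count, sense$start, sum)
    counts[as.integer(names(agg))] <- as.numeric(agg)
  }
  structure(list(transcript = transcript_id, counts = counts),
            class = "phasilens_tplot")
}

#' Cleavage category of one T-plot position
#'
#' Categories (degradome convention): 4 if the count is 1; 0 if > 1 and the
#' unique transcript-wide maximum; 1 if > 1, equal to the maximum but the
#' maximum is attained elsewhere too; 2 if > 1, below the maximum and above
#' the median of the non-zero positions; 3 if > 1 and at or below that
#' median. A zero count is an error ("no cleavage evidence").
#'
#' @param tplot object from [build_tplot()].
#' @param pos 1-based transcript position.
#' @return integer category 0-4.
#' @export
categorize_position <- function(tplot, pos) {
  counts <- tplot$counts
  if (pos < 1L || pos > length(counts)) stop("position out of range", call. = FALSE)
  x <- counts[pos]
  if (x == 0) stop("no cleavage evidence at this position", call. = FALSE)
  if (x == 1) return(4L)
  mx <- max(counts)
  if (x == mx) {
    if (sum(counts == mx) == 1L) return(0L) else return(1L)
  }
  med <- stats::median(counts[counts > 0])
  if (x > med) 2L else 3L
}

#' Detect candidate slice sites on a transcript
#'
#' Scans every fixed-length window of the transcript against the miRNA,
#' keeps windows with duplex penalty at most `penalty_max`, computes the
#' slice position as the transcript base paired with miRNA nucleotide 10
#' (for a site spanning s..e, `slice = e - 9`), and reports sites whose
#' slice position carries at least one read 5' end with cleavage category
#' at most `category_max`, sorted by (category, penalty).
#'
#' @param mirna miRNA sequence.
#' @param transcript transcript sequence.
#' @param aln transcript alignments (for the T-plot).
#' @param penalty_max duplex penalty cutoff (default 7).
#' @param category_max maximum admissible cleavage category (default 4).
#' @param transcript_id optional id for the report.
#' @return data.frame (transcript, site_start, site_end, penalty,
#'   slice_position, slice_count, category); zero rows when the transcript
#'   is shorter than the miRNA or nothing passes.
#' @export
detect_slice_sites <- function(mirna, transcript, aln, penalty_max = 7,
                               category_max = 4L,
                               transcript_id = NA_character_) {
  empty <- data.frame(transcript = character(0), site_start = integer(0),
                      site_end = integer(0), penalty = numeric(0),
                      slice_position = integer(0), slice_count = numeric(0),
                      category = integer(0), stringsAsFactors = FALSE)
  n <- nchar(mirna)
  L <- nchar(transcript)
  if (L < n) return(empty)
  tplot <- build_tplot(aln, L, transcript_id)
  out <- list()
  for (s in seq_len(L - n + 1L)) {
    e <- s + n - 1L
    pen <- score_duplex(mirna, substr(transcript, s, e))$penalty
    if (pen > penalty_max) next
    slice <- e - 9L
    cnt <- tplot$counts[slice]
    if (cnt < 1) next
    cat <- categorize_position(tplot, slice)
    if (cat > category_max) next
    out[[length(out) + 1L]] <- data.frame(
      transcript = transcript_id, site_start = s, site_end = e,
      penalty = pen, slice_position = slice, slice_count = cnt,
      category = cat, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res[order(res$category, res$penalty, res$site_start), , drop = FALSE]
}

#' T-plot data as a plain table
#'
#' @param tplot object from [build_tplot()].
#' @return data.frame (position, count) restricted to non-zero positions.
#' @export
tplot_table <- function(tplot) {
  nz <- which(tplot$counts > 0)
  data.frame(position = nz, count = tplot$counts[nz])
}
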