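# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (and the libraries backing them) so that agreement is a
# real check, not a tautology.

oracle_can_pair <- function(a, b) {
  paste0(a, b) %in% c("AT", "TA", "CG", "GC", "GT", "TG")
}

# Exhaustive maximum-pairing count by plain recursion over all nested
# structures (first position unpaired, or paired to every admissible k).
oracle_max_pairs <- function(seq, min_loop = 3L) {
  b <- strsplit(toupper(chartr("U", "T", seq)), "")[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (j - i < min_loop + 1L) return(0L)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- rec(i + 1L, j)
    for (k in seq(i + min_loop + 1L, j)) {
      if (oracle_can_pair(b[i], b[k])) {
        best <- max(best, 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j))
      }
    }
    memo[[key]] <- best
    best
  }
  rec(1L, length(b))
}

# All-positions scan aligner (both strands, substitutions only).
oracle_scan_align <- function(read, genome_chr, max_mm = 1L) {
  revcomp_chr <- function(x) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
  }
  gb <- strsplit(genome_chr, "")[[1]]
  hits <- list()
  for (std in c("+", "-")) {
    pat <- if (std == "+") read else revcomp_chr(read)
    pb <- strsplit(pat, "")[[1]]
    L <- length(pb)
    np <- length(gb) - L + 1L
    if (np < 1L) next
    mm <- rep(0L, np)
    for (i in seq_len(L)) mm <- mm + (gb[seq(i, i + np - 1L)] != pb[i])
    for (pos in which(mm <= max_mm)) {
      hits[[length(hits) + 1L]] <- data.frame(
        start = pos, end = pos + L - 1L, strand = std,
        mismatches = mm[pos], stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0)))
  }
  do.call(rbind, hits)
}

# Coverage-array clustering oracle (integer loop, fractional weights).
oracle_clusters <- function(aln, seqlen, mincov) {
  cov <- rep(0, seqlen)
  for (r in seq_len(nrow(aln))) {
    idx <- aln$start[r]:aln$end[r]
    cov[idx] <- cov[idx] + aln$count[r] / aln$n_hits[r]
  }
  res <- list()
  p <- 1L
  while (p <= seqlen) {
    if (cov[p] > 0) {
      q <- p
      while (q < seqlen && cov[q + 1L] > 0) q <- q + 1L
      if (max(cov[p:q]) >= mincov) {
        res[[length(res) + 1L]] <- c(p, q)
      }
      p <- q + 1L
    } else p <- p + 1L
  }
  res
}

# Cleavage-category oracle, re-derived from the stated definitions.
oracle_category <- function(counts, pos) {
  x <- counts[pos]
  if (x == 0) return(NA_integer_)
  if (x == 1) return(4L)
  mx <- max(counts)
  nz <- counts[counts > 0]
  if (x == mx && sum(counts == mx) == 1) return(0L)
  if (x == mx) return(1L)
  if (x > median(nz)) return(2L) else return(3L)
}

# Phase-score oracle: independent re-derivation of the formula on an
# explicit per-read loop.
oracle_phase_score <- function(starts, ends, strands, counts, lens, s,
                               period = 21L, k_min = 3L, window_cycles = 10L) {
  P <- 0; U <- 0; regs <- integer(0)
  for (r in seq_along(starts)) {
    fp <- if (strands[r] == "+") starts[r] else ends[r]
    if (fp < s || fp > s + period * window_cycles - 1L) next
    if (lens[r] < 20L || lens[r] > 22L) next
    off <- if (strands[r] == "+") starts[r] - s
           else ends[r] - s - (period - 3L)
    if (off %% period == 0L) {
      P <- P + counts[r]
      regs <- c(regs, off %/% period)
    } else U <- U + counts[r]
  }
  k <- length(unique(regs))
  if (k < k_min) return(list(score = 0, k = k, P = P, U = U))
  list(score = (k - 2) * log(1 + 10 * P / (1 + U)), k = k, P = P, U = U)
}

# Allen-style duplex penalty oracle: position-by-position tally.
oracle_duplex_penalty <- function(mirna, window) {
  mb <- strsplit(toupper(chartr("U", "T", mirna)), "")[[1]]
  wb <- strsplit(toupper(chartr("U", "T", window)), "")[[1]]
  n <- length(mb)
  pen <- 0
  for (i in seq_len(n)) {
    t <- wb[n - i + 1L]
    c0 <- if (paste0(mb[i], t) %in% c("AT", "TA", "CG", "GC")) 0
          else if (paste0(mb[i], t) %in% c("GT", "TG")) 0.5
          else 1
    pen <- pen + if (i >= 2 && i <= 13) 2 * c0 else c0
  }
  pen
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
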