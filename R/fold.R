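# Base-pair-maximisation secondary-structure folding (Nussinov-style DP,
# Watson-Crick plus G:U wobble), used in place of thermodynamic MFE folding
# for hairpin evaluation. Maximum-cardinality structures are highly
# degenerate, so ties are broken deterministically by maximising the number
# of stacked pairs (pairs whose neighbour (i+1, j-1) is also paired) - a
# discrete surrogate for stacking energy that makes the recovered structure
# of a clean hairpin its long duplex helix rather than an arbitrary
# equal-cardinality rearrangement. Remaining ties fall to the smallest
# admissible partner, preferring a stacked continuation.

can_pair_base <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
  (a == "C" & b == "G") | (a == "G" & b == "C") |
  (a == "G" & b == "T") | (a == "T" & b == "G")
}

# Lexicographic (count, stacks) objective packed into one numeric:
# count * 1024 + stacks; stacks < count <= n/2 < 1024 for foldsize <= 340.
PAIR_UNIT <- 1024

#' Maximum base-pairing structure of a sequence window
#'
#' Computes a maximum-cardinality nested pairing (no pseudoknots) with
#' hairpin loops of at least `min_loop` unpaired bases, over Watson-Crick
#' and G:U pairs. U and T are equivalent. Among maximum-cardinality
#' structures, one maximising the number of stacked pairs is returned,
#' deterministically (see file header).
#'
#' @param seq DNA or RNA string, length at most `foldsize`.
#' @param min_loop minimum hairpin loop length (default 3).
#' @param foldsize maximum admissible window length (default 340).
#' @return data.frame with columns `i`, `j` (1-based paired positions,
#'   `i < j`), zero rows when nothing pairs.
#' @export
fold_window <- function(seq, min_loop = 3L, foldsize = 340L) {
  seq <- toupper(chartr("U", "T", seq))
  n <- nchar(seq)
  if (n > foldsize) {
    stop(sprintf("window of %d nt exceeds foldsize %d", n, foldsize),
         call. = FALSE)
  }
  if (min_loop < 3L) stop("min_loop must be >= 3", call. = FALSE)
  empty <- data.frame(i = integer(0), j = integer(0))
  if (n < min_loop + 2L) return(empty)
  b <- strsplit(seq, "")[[1]]
  can <- outer(b, b, can_pair_base)

  FF <- matrix(0, n, n)      # best (count, stacks) over [i, j]
  CC <- matrix(-Inf, n, n)   # best given (i, j) paired
  for (j in seq(min_loop + 2L, n)) {
    ks <- seq_len(j - min_loop - 1L)
    # C column: 1 pair + interior, interior either continues the helix
    # ((k+1, j-1) paired, stacking bonus) or is any structure without it
    inner_stacked <- CC[cbind(ks + 1L, j - 1L)] + 1
    inner_free <- FF[cbind(ks + 1L, j - 1L)]
    cc <- PAIR_UNIT + pmax(inner_stacked, inner_free)
    cc[!can[cbind(ks, rep(j, length(ks)))]] <- -Inf
    CC[ks, j] <- cc
    for (i in seq(j - min_loop - 1L, 1L)) {
      best <- FF[i, j - 1L]
      kk <- ks[ks >= i & is.finite(CC[ks, j])]
      if (length(kk)) {
        left <- ifelse(kk > i, FF[cbind(pmax(i, 1L), pmax(kk - 1L, 1L))], 0)
        best <- max(best, CC[kk, j] + left)
      }
      FF[i, j] <- best
    }
  }

  pairs <- matrix(integer(0), ncol = 2)
  stack <- list(c(1L, n, 0L))  # (i, j, closed?) closed=1 means (i,j) paired
  while (length(stack)) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- fr[1]; j <- fr[2]
    if (fr[3] == 1L) {
      pairs <- rbind(pairs, c(i, j))
      if (is.finite(CC[i + 1L, j - 1L]) &&
          CC[i, j] == PAIR_UNIT + CC[i + 1L, j - 1L] + 1) {
        stack[[length(stack) + 1L]] <- c(i + 1L, j - 1L, 1L)
      } else {
        stack[[length(stack) + 1L]] <- c(i + 1L, j - 1L, 0L)
      }
      next
    }
    while (j - i >= min_loop + 1L && FF[i, j] > 0) {
      if (FF[i, j] == FF[i, j - 1L]) { j <- j - 1L; next }
      done <- FALSE
      for (k in seq(i, j - min_loop - 1L)) {
        if (!is.finite(CC[k, j])) next
        left <- if (k > i) FF[i, k - 1L] else 0
        if (CC[k, j] + left == FF[i, j]) {
          stack[[length(stack) + 1L]] <- c(k, j, 1L)
          if (k > i) stack[[length(stack) + 1L]] <- c(i, k - 1L, 0L)
          done <- TRUE
          break
        }
      }
      if (!done) j <- j - 1L  # unreachable by construction, kept defensive
      else break
    }
  }
  if (nrow(pairs) == 0L) return(empty)
  out <- data.frame(i = pairs[, 1], j = pairs[, 2])
  out <- out[order(out$i), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Dot-bracket rendering of a pairing
#'
#' @param seq the folded sequence.
#' @param pairs data.frame from [fold_window()].
#' @return a two-line character vector (sequence, structure).
#' @export
render_dotbracket <- function(seq, pairs) {
  db <- rep(".", nchar(seq))
  db[pairs$i] <- "("
  db[pairs$j] <- ")"
  c(seq, paste(db, collapse = ""))
}
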