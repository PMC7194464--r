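# sRNA library preprocessing: 3' adapter trimming, length filtering, read
# collapsing and reads-per-million normalisation. The collapsed-FASTA
# dialect uses headers ">tK_xN" (K = abundance rank, N = count).

#' Trim a 3' adapter and filter short reads
#'
#' Removes everything from the leftmost exact occurrence of the full adapter
#' onward; if the full adapter does not occur, falls back to the longest
#' adapter prefix (>= 8 nt) matching exactly at the read 3' end. Reads whose
#' trimmed length falls below `min_len` are discarded (returned as `NA`).
#' Matching is exact (no mismatches).
#'
#' @param reads character vector of read sequences (A/C/G/T/N).
#' @param adapter non-empty adapter sequence.
#' @param min_len minimum retained insert length (default 18).
#' @param min_prefix minimum adapter-prefix length for the 3'-end fallback.
#' @return character vector: trimmed inserts, `NA` where discarded.
#' @export
trim_and_filter <- function(reads, adapter, min_len = 18L, min_prefix = 8L) {
  if (!nzchar(adapter)) stop("adapter must be non-empty", call. = FALSE)
  if (min_len < 1L) stop("min_len must be >= 1", call. = FALSE)
  assert_dna(reads, "read")
  assert_dna(adapter, "adapter")
  out <- vapply(reads, function(r) {
    hit <- regexpr(adapter, r, fixed = TRUE)
    if (hit > 0L) {
      r <- substr(r, 1L, hit - 1L)
    } else {
      kmax <- min(nchar(adapter), nchar(r))
      if (kmax >= min_prefix) {
        for (k in seq(kmax, min_prefix)) {
          if (substr(r, nchar(r) - k + 1L, nchar(r)) == substr(adapter, 1L, k)) {
            r <- substr(r, 1L, nchar(r) - k)
            break
          }
        }
      }
    }
    r
  }, character(1), USE.NAMES = FALSE)
  out[nchar(out) < min_len] <- NA_character_
  out
}

#' Collapse reads to unique sequences with counts
#'
#' @param reads character vector of read sequences (`NA`s dropped).
#' @return data.frame (sequence, length, count), ordered by decreasing count
#'   then sequence; `collapse_reads(character(0))` is an empty frame.
#' @export
collapse_reads <- function(reads) {
  reads <- reads[!is.na(reads)]
  if (length(reads) == 0L) {
    return(data.frame(sequence = character(0), length = integer(0),
                      count = integer(0), stringsAsFactors = FALSE))
  }
  tab <- table(reads)
  df <- data.frame(sequence = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$sequence), , drop = FALSE]
  rownames(df) <- NULL
  data.frame(sequence = df$sequence, length = nchar(df$sequence),
             count = df$count, stringsAsFactors = FALSE)
}

#' Expand collapsed reads back to one entry per read
#'
#' Inverse of [collapse_reads()] up to ordering: the result is a permutation
#' of the original read multiset.
#'
#' @param collapsed data.frame from [collapse_reads()].
#' @return character vector.
#' @export
expand_reads <- function(collapsed) {
  rep(collapsed$sequence, collapsed$count)
}

#' Reads-per-million normalisation
#'
#' `rpm = count / library_total * 1e6`. With `library_total = sum(count)`
#' (the default) the rpm column sums to exactly one million.
#'
#' @param collapsed data.frame with a `count` column.
#' @param library_total total mapped/retained reads in the library.
#' @return the input with an `rpm` column added.
#' @export
rpm_normalize <- function(collapsed, library_total = sum(collapsed$count)) {
  if (length(library_total) != 1L || library_total <= 0) {
    stop("library_total must be a single positive number", call. = FALSE)
  }
  if (library_total < sum(collapsed$count)) {
    stop("library_total is smaller than the summed counts", call. = FALSE)
  }
  collapsed$rpm <- collapsed$count / library_total * 1e6
  collapsed
}

#' Write collapsed reads as collapsed FASTA (">tK_xN" dialect)
#'
#' @param collapsed data.frame from [collapse_reads()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_collapsed_fasta <- function(collapsed, path) {
  x <- Biostrings::DNAStringSet(collapsed$sequence)
  names(x) <- sprintf("t%d_x%d", seq_len(nrow(collapsed)), collapsed$count)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read collapsed FASTA written in the ">tK_xN" dialect
#'
#' @param path collapsed FASTA path.
#' @return data.frame (sequence, length, count).
#' @export
read_collapsed_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  counts <- as.integer(sub("^t\\d+_x(\\d+)$", "\\1", names(x)))
  if (anyNA(counts)) stop("headers are not in the tK_xN dialect", call. = FALSE)
  data.frame(sequence = as.character(x), length = Biostrings::width(x),
             count = counts, stringsAsFactors = FALSE)
}

#' Preprocess a FASTQ sRNA library
#'
#' Trim, length-filter, collapse and rpm-normalise one library.
#'
#' @param fastq path to a FASTQ file.
#' @param adapter 3' adapter sequence.
#' @param min_len minimum insert length.
#' @return data.frame (sequence, length, count, rpm).
#' @export
preprocess_library <- function(fastq, adapter = ADAPTER_SEQ, min_len = 18L) {
  raw <- as.character(Biostrings::readDNAStringSet(fastq, format = "fastq"))
  trimmed <- trim_and_filter(raw, adapter, min_len)
  n_kept <- sum(!is.na(trimmed))
  collapsed <- collapse_reads(trimmed)
  if (n_kept == 0L) {
    collapsed$rpm <- numeric(0)
    return(collapsed)
  }
  rpm_normalize(collapsed, n_kept)
}
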