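# Shared low-level helpers: sequence manipulation, seeded RNG streams,
# small validators. All coordinates in this package are 1-based inclusive
# (IRanges convention); GFF3/SAM outputs are 1-based by format.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Derive a stream seed from a global seed and an operation name
#'
#' Each simulation stage draws from its own RNG stream seeded by the global
#' seed and a hash of the operation name, so stages are independently
#' reproducible. The result is kept inside 32-bit integer range.
#'
#' @param seed integer global seed.
#' @param op character operation name.
#' @return integer seed.
#' @export
derive_seed <- function(seed, op) {
  h <- 0
  for (ch in utf8ToInt(op)) h <- (h * 131 + ch) %% 1000003L
  as.integer((abs(as.numeric(seed)) %% 65521 + 1) * 2654 + h) %% .Machine$integer.max
}

assert_dna <- function(x, what = "sequence", allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    stop(sprintf("%s contains non-%s characters (first offender: %s)",
                 what, if (allow_n) "ACGTN" else "ACGT",
                 x[bad][1]), call. = FALSE)
  }
  invisible(x)
}

# sample() with a private RNG state, leaving the caller's stream untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

# Deterministic TSV writers: no quoting, no row names, "." decimal.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, ...)
}

# Simple deterministic parameter hash for log lines / manifests.
param_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 0xFFFFFF
  sprintf("%06x", h)
}

stage_log <- function(stage, seed, params, msg) {
  message(sprintf("[%s] seed=%s params=%s %s", stage,
                  as.character(seed), param_hash(params), msg))
}
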