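# Codon-level comparison of two equal-length coding sequences and
# in-frame trinucleotide-repeat counting (standard nuclear genetic code,
# residues numbered from the initiator methionine).

codon_table <- function() Biostrings::GENETIC_CODE

translate_codon <- function(codon) {
  aa <- codon_table()[codon]
  ifelse(is.na(aa), "X", aa)
}

split_codons <- function(cds) {
  substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
}

validate_cds <- function(cds, what) {
  assert_dna(cds, what, allow_n = FALSE)
  if (nchar(cds) %% 3L != 0L) {
    stop(sprintf("%s length is not a multiple of 3", what), call. = FALSE)
  }
  if (substr(cds, 1L, 3L) != "ATG") {
    stop(sprintf("%s does not start with ATG", what), call. = FALSE)
  }
  last <- substr(cds, nchar(cds) - 2L, nchar(cds))
  if (!last %in% c("TAA", "TAG", "TGA")) {
    stop(sprintf("%s does not end at a stop codon", what), call. = FALSE)
  }
  invisible(cds)
}

#' Compare two same-length coding sequences codon by codon
#'
#' Both sequences must start with ATG, end at a stop codon and have equal
#' lengths that are multiples of 3 (frameshifted inputs are rejected:
#' frame restoration is manual preprocessing, not an algorithm here).
#' Differing codons are classed `silent` (same residue), `nonsense` (the
#' alternate residue is a stop) or `missense`.
#'
#' @param cds_a,cds_b reference and alternate CDS (DNA strings).
#' @return list with `diffs` (residue, ref_codon, alt_codon, ref_aa,
#'   alt_aa, class) and `summary` (n_silent, n_missense, n_nonsense).
#' @export
compare_orfs <- function(cds_a, cds_b) {
  validate_cds(cds_a, "cds_a")
  validate_cds(cds_b, "cds_b")
  if (nchar(cds_a) != nchar(cds_b)) {
    stop("coding sequences differ in length", call. = FALSE)
  }
  ca <- split_codons(cds_a)
  cb <- split_codons(cds_b)
  idx <- which(ca != cb)
  aa_a <- translate_codon(ca[idx])
  aa_b <- translate_codon(cb[idx])
  class <- ifelse(aa_a == aa_b, "silent",
           ifelse(aa_b == "*", "nonsense", "missense"))
  diffs <- data.frame(residue = idx, ref_codon = ca[idx], alt_codon = cb[idx],
                      ref_aa = aa_a, alt_aa = aa_b, class = class,
                      stringsAsFactors = FALSE)
  list(diffs = diffs,
       summary = c(n_silent = sum(class == "silent"),
                   n_missense = sum(class == "missense"),
                   n_nonsense = sum(class == "nonsense")))
}

#' Length of an in-frame trinucleotide codon repeat
#'
#' Counts the maximal run of consecutive in-frame occurrences of `motif`
#' starting at `start_residue` (1-based from the initiator methionine).
#'
#' @param cds coding sequence.
#' @param motif trinucleotide motif (e.g. "GGC").
#' @param start_residue first residue of the run.
#' @return integer run length (0 if the motif is absent at `start_residue`).
#' @export
count_codon_repeat <- function(cds, motif, start_residue) {
  if (nchar(motif) != 3L) stop("motif must be a trinucleotide", call. = FALSE)
  codons <- split_codons(cds)
  if (start_residue < 1L || start_residue > length(codons)) {
    stop("start_residue out of range", call. = FALSE)
  }
  n <- 0L
  for (i in seq(start_residue, length(codons))) {
    if (codons[i] == motif) n <- n + 1L else break
  }
  n
}
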