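# Synthetic truth-set generator: a toy genome carrying (i) a MIRNA hairpin
# whose 5' arm encodes a 21-nt mature sRNA (with a minor 22-nt 3'-extended
# species, mostly non-templated mono-U), (ii) a three-exon target gene whose
# mRNA carries a near-complementary miRNA site sliced opposite miRNA
# nucleotide 10, with sense/antisense 21-nt phased siRNAs downstream of the
# slice site (2-nt 3' overhangs), and (iii) uniform background sRNA noise.
# Everything downstream of the generator is validated against this truth.

# Fixed synthetic mature sequence (arbitrary; NOT the real aco-miR828, whose
# sequence is not modelled here). Ends in AA so that both duplex 3'
# overhangs are A/A and cannot pair with the A/C-only hairpin flanks: the
# maximum base-pairing structure of the hairpin window is then exactly the
# 19-bp mature:star duplex, making fold-based evaluation deterministic.
SYNTH_MATURE <- "TCGGACTGTTAGCATCCTGAA"
SYNTH_LOOP   <- "CCCCACCCCACCCCA"
ADAPTER_SEQ  <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA"

#' Default generator configuration
#'
#' Values mirror the stated world of the analysis: 21-nt phasing period,
#' eight phased cycles, 0.93 mono-uridylation probability for the 22-nt
#' mature species, introns of 1113 and 1340 nt in the target gene, and
#' background noise spanning the analysed 18-26-nt size range.
#'
#' @return named list of generator parameters.
#' @export
synth_default_config <- function() {
  list(
    period        = 21L,
    n_cycles      = 8L,
    sense_fraction = 0.5,
    p_mono_U      = 0.93,
    depth         = 1,
    noise_reads   = 200L,
    noise_len_min = 18L,
    noise_len_max = 26L,
    mature21_count = 120L,
    mature22_count = 40L,
    star_count     = 20L,
    phased_base    = 10L,
    d1_boost       = 30L,
    intron_lengths = c(1113L, 1340L),
    exon_lengths   = c(400L, 150L, 150L),
    site_start     = 101L,
    rnaseq_target_reads = 60L,
    rnaseq_mirna_reads  = 30L,
    rnaseq_read_len     = 100L,
    penalty_max    = 7,
    min_loop       = 3L
  )
}

pad_ac <- function(n) paste(sample(c("A", "C"), n, replace = TRUE), collapse = "")

#' Build the synthetic truth set
#'
#' Constructs the toy genome, its loci and all generative parameters.
#' Deterministic for a fixed (config, seed). If `dir` is given, writes
#' `genome.fa`, `loci.gff3` and `truth.tsv` there.
#'
#' @param config named list overriding [synth_default_config()] entries.
#' @param seed integer seed.
#' @param dir optional output directory.
#' @return an object of class `phasilens_truth`.
#' @export
build_truth_set <- function(config = list(), seed = 1L, dir = NULL) {
  cfg <- utils::modifyList(synth_default_config(), config)
  if (cfg$n_cycles < 1L || cfg$period < 18L) {
    stop("invalid config: need n_cycles >= 1 and period >= 18", call. = FALSE)
  }
  mature <- SYNTH_MATURE
  star <- paste0(revcomp(substr(mature, 1L, 19L)), "AA")
  hairpin <- paste0(mature, SYNTH_LOOP, star)

  truth <- with_seed(derive_seed(seed, "truth"), {
    bg1 <- random_dna(300L)
    padL <- pad_ac(170L)
    padR <- pad_ac(170L)
    bg2 <- random_dna(200L)

    ex_len <- cfg$exon_lengths
    exon1 <- random_dna(ex_len[1])
    # plant miRNA sites pair antiparallel: miRNA position i pairs transcript
    # position site_end - i + 1; a perfect-complement site is revcomp(mature)
    # with one G:U wobble introduced opposite miRNA position 15.
    site <- revcomp(mature)
    substr(site, 7L, 7L) <- "G"   # pairs mature[15] = T as a T:G wobble
    s0 <- cfg$site_start
    substr(exon1, s0, s0 + nchar(site) - 1L) <- site
    introns <- vapply(cfg$intron_lengths, random_dna, character(1))
    exon2 <- random_dna(ex_len[2])
    exon3 <- random_dna(ex_len[3])
    bg3 <- random_dna(200L)

    chr1 <- paste0(bg1, padL, hairpin, padR, bg2,
                   exon1, introns[1], exon2, introns[2], exon3, bg3)

    hp_start <- nchar(bg1) + nchar(padL) + 1L
    gene_start <- nchar(bg1) + nchar(padL) + nchar(hairpin) +
      nchar(padR) + nchar(bg2) + 1L
    exon_starts <- c(gene_start,
                     gene_start + ex_len[1] + cfg$intron_lengths[1],
                     gene_start + ex_len[1] + cfg$intron_lengths[1] +
                       ex_len[2] + cfg$intron_lengths[2])
    exon_ends <- exon_starts + ex_len - 1L

    transcript <- paste0(exon1, exon2, exon3)
    site_end <- s0 + nchar(mature) - 1L
    slice <- site_end - 9L  # transcript base paired to miRNA nt 10

    list(
      genome = c(chr1 = chr1),
      mirna_locus = list(
        seqid = "chr1", strand = "+",
        start = hp_start, end = hp_start + nchar(hairpin) - 1L,
        mature_start = hp_start, mature_end = hp_start + nchar(mature) - 1L,
        star_start = hp_start + nchar(mature) + nchar(SYNTH_LOOP),
        star_end = hp_start + nchar(hairpin) - 1L,
        mature_seq = mature, star_seq = star,
        next_base = substr(SYNTH_LOOP, 1L, 1L)
      ),
      target_gene = list(
        seqid = "chr1", strand = "+", id = "TGT1",
        start = gene_start, end = exon_ends[3],
        exon_starts = exon_starts, exon_ends = exon_ends,
        transcript = transcript,
        site_start = s0, site_end = site_end,
        slice_position = slice
      ),
      intron_lengths = cfg$intron_lengths,
      phasing_params = list(period = cfg$period, n_cycles = cfg$n_cycles,
                            sense_fraction = cfg$sense_fraction),
      tail_params = list(p_mono_U = cfg$p_mono_U),
      noise_params = list(noise_reads = cfg$noise_reads,
                          len_range = c(cfg$noise_len_min, cfg$noise_len_max)),
      config = cfg,
      seed = as.integer(seed)
    )
  })
  class(truth) <- "phasilens_truth"
  validate_truth_set(truth)
  if (!is.null(dir)) write_truth_set(truth, dir)
  truth
}

validate_truth_set <- function(truth) {
  tg <- truth$target_gene
  ml <- truth$mirna_locus
  L <- nchar(truth$genome[[1]])
  stopifnot(
    tg$slice_position == tg$site_end - 9L,
    ml$mature_end <= L, ml$star_end <= L, tg$end <= L, tg$start >= 1L
  )
  hairpin <- substr(truth$genome[[ml$seqid]], ml$start, ml$end)
  if (!grepl(ml$mature_seq, hairpin, fixed = TRUE) ||
      !grepl(ml$star_seq, hairpin, fixed = TRUE)) {
    stop("mature/star are not substrings of the hairpin", call. = FALSE)
  }
  # the miRNA nt-10 pairing defines the slice site: check by direct pairing
  site <- substr(tg$transcript, tg$site_start, tg$site_end)
  stopifnot(nchar(site) == nchar(ml$mature_seq))
  # the generated site must score under the target-prediction cutoff
  pen <- score_duplex(ml$mature_seq, site)$penalty
  if (pen > truth$config$penalty_max) {
    stop("generated target site exceeds the duplex penalty cutoff", call. = FALSE)
  }
  invisible(truth)
}

truth_gff <- function(truth) {
  ml <- truth$mirna_locus
  tg <- truth$target_gene
  gr <- GenomicRanges::GRanges(
    seqnames = "chr1",
    ranges = IRanges::IRanges(
      start = c(ml$start, ml$mature_start, ml$star_start,
                tg$start, tg$start, tg$exon_starts),
      end = c(ml$end, ml$mature_end, ml$star_end,
              tg$end, tg$end, tg$exon_ends)),
    strand = c(rep("+", 3L), rep(tg$strand, 2L + length(tg$exon_starts))),
    type = c("MIRNA_primary_transcript", "miRNA", "miRNA_star",
             "gene", "mRNA", rep("exon", length(tg$exon_starts))),
    ID = c("MIR1", "MIR1_mature", "MIR1_star", "TGT1", "TGT1.1",
           paste0("TGT1.1.exon", seq_along(tg$exon_starts))),
    Parent = c(NA, "MIR1", "MIR1", NA, "TGT1",
               rep("TGT1.1", length(tg$exon_starts)))
  )
  gr
}

#' Write a truth set to disk
#'
#' Emits `genome.fa`, `loci.gff3` and `truth.tsv` (one row per truth fact:
#' loci, target site, slice position, every expected phase position, introns).
#'
#' @param truth a `phasilens_truth` object.
#' @param dir output directory (created if absent).
#' @return invisibly, the directory.
#' @export
write_truth_set <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gen <- Biostrings::DNAStringSet(truth$genome)
  Biostrings::writeXStringSet(gen, file.path(dir, "genome.fa"))
  rtracklayer::export(truth_gff(truth), file.path(dir, "loci.gff3"),
                      format = "gff3")

  tg <- truth$target_gene
  pp <- truth$phasing_params
  k <- seq_len(pp$n_cycles) - 1L
  s <- tg$slice_position
  rows <- rbind(
    data.frame(type = "mirna_mature", coord_space = "genome",
               start = truth$mirna_locus$mature_start,
               end = truth$mirna_locus$mature_end, strand = "+",
               note = truth$mirna_locus$mature_seq),
    data.frame(type = "mirna_star", coord_space = "genome",
               start = truth$mirna_locus$star_start,
               end = truth$mirna_locus$star_end, strand = "+",
               note = truth$mirna_locus$star_seq),
    data.frame(type = "target_site", coord_space = "transcript",
               start = tg$site_start, end = tg$site_end, strand = "+",
               note = tg$id),
    data.frame(type = "slice_position", coord_space = "transcript",
               start = s, end = s, strand = "+", note = tg$id),
    data.frame(type = "phase_sense", coord_space = "transcript",
               start = s + pp$period * k, end = s + pp$period * k +
                 pp$period - 1L, strand = "+",
               note = paste0("D", k + 1L, "(+)")),
    data.frame(type = "phase_antisense", coord_space = "transcript",
               start = s + pp$period * k - 2L,
               end = s + pp$period * k + pp$period - 3L, strand = "-",
               note = paste0("D", k + 1L, "(-)")),
    data.frame(type = "intron", coord_space = "genome",
               start = tg$exon_ends[-length(tg$exon_ends)] + 1L,
               end = tg$exon_starts[-1L] - 1L, strand = "+",
               note = paste0("len=", truth$intron_lengths))
  )
  write_tsv(rows, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Simulate a small-RNA library from a truth set
#'
#' Emits phased 21-nt reads on both strands (antisense 5' ends offset by the
#' 2-nt 3' overhang rule), mature-miRNA reads of which `p_mono_U` of the
#' 22-nt species carry a non-templated 3' U, star reads, and uniform
#' background noise. Every read is labelled. If `dir` is given, writes
#' `reads.fastq` (3' adapter appended, constant quality "I") and
#' `labels.tsv`.
#'
#' @param truth a `phasilens_truth` object.
#' @param depth positive multiplier on all configured read counts.
#' @param seed integer seed.
#' @param adapter 3' adapter ligated to each read in the FASTQ output.
#' @param dir optional output directory.
#' @return data.frame with columns read_id, sequence, label.
#' @export
simulate_srna_library <- function(truth, depth = 1, seed = 1L,
                                  adapter = ADAPTER_SEQ, dir = NULL) {
  stopifnot(inherits(truth, "phasilens_truth"))
  if (!is.numeric(depth) || depth <= 0) stop("depth must be > 0", call. = FALSE)
  cfg <- truth$config
  ml <- truth$mirna_locus
  tg <- truth$target_gene
  pp <- truth$phasing_params

  with_seed(derive_seed(seed, "srna"), {
    seqs <- character(0); labels <- character(0)
    add <- function(seq, n, label) {
      if (n > 0L) {
        seqs <<- c(seqs, rep(seq, n))
        labels <<- c(labels, rep(label, n))
      }
    }
    n21 <- round(cfg$mature21_count * depth)
    n22 <- round(cfg$mature22_count * depth)
    n_u <- if (n22 > 0L) rbinom(1L, n22, truth$tail_params$p_mono_U) else 0L
    add(ml$mature_seq, n21, "mirna")
    add(paste0(ml$mature_seq, "T"), n_u, "mirna_tailed")
    add(paste0(ml$mature_seq, ml$next_base), n22 - n_u, "mirna")
    add(ml$star_seq, round(cfg$star_count * depth), "mirna")

    s <- tg$slice_position; p <- pp$period
    cyc_total <- 2L * cfg$phased_base
    n_sense <- round(cyc_total * pp$sense_fraction)
    n_anti <- cyc_total - n_sense
    for (k in seq_len(pp$n_cycles) - 1L) {
      sense <- substr(tg$transcript, s + p * k, s + p * k + p - 1L)
      anti <- revcomp(substr(tg$transcript, s + p * k - 2L, s + p * k + p - 3L))
      ns <- round((n_sense + if (k == 0L) cfg$d1_boost else 0L) * depth)
      add(sense, ns, "phased_sense")
      add(anti, round(n_anti * depth), "phased_antisense")
    }

    n_noise <- round(truth$noise_params$noise_reads * depth)
    if (n_noise > 0L) {
      L <- nchar(truth$genome[[1]])
      lens <- sample(seq(truth$noise_params$len_range[1],
                         truth$noise_params$len_range[2]),
                     n_noise, replace = TRUE)
      starts <- vapply(lens, function(l) sample.int(L - l + 1L, 1L), integer(1))
      strands <- sample(c("+", "-"), n_noise, replace = TRUE)
      nseq <- substr(rep(truth$genome[[1]], n_noise), starts, starts + lens - 1L)
      nseq[strands == "-"] <- revcomp(nseq[strands == "-"])
      seqs <- c(seqs, nseq)
      labels <- c(labels, rep("noise", n_noise))
    }

    ord <- sample.int(length(seqs))
    reads <- data.frame(
      read_id = sprintf("r%06d", seq_along(seqs)),
      sequence = seqs[ord],
      label = labels[ord],
      stringsAsFactors = FALSE
    )
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      raw <- Biostrings::DNAStringSet(paste0(reads$sequence, adapter))
      names(raw) <- reads$read_id
      quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(raw)))
      Biostrings::writeXStringSet(raw, file.path(dir, "reads.fastq"),
                                  format = "fastq", qualities = quals)
      write_tsv(reads, file.path(dir, "labels.tsv"))
    }
    reads
  })
}

# map a transcript interval [t0, t0+len-1] onto the genome through the exon
# chain; returns genomic pos of the first base and a CIGAR with N skips.
transcript_to_genomic_cigar <- function(tg, t0, len) {
  ex_len <- tg$exon_ends - tg$exon_starts + 1L
  t_off <- cumsum(c(0L, ex_len))   # transcript offset at exon starts
  remaining <- len
  tpos <- t0
  cig <- character(0)
  gpos <- NA_integer_
  while (remaining > 0L) {
    ei <- findInterval(tpos, t_off[-length(t_off)] + 1L)
    in_ex <- tpos - t_off[ei]                 # 1-based within exon
    avail <- ex_len[ei] - in_ex + 1L
    take <- min(avail, remaining)
    g <- tg$exon_starts[ei] + in_ex - 1L
    if (is.na(gpos)) gpos <- g
    cig <- c(cig, paste0(take, "M"))
    remaining <- remaining - take
    tpos <- tpos + take
    if (remaining > 0L) {
      intron <- tg$exon_starts[ei + 1L] - tg$exon_ends[ei] - 1L
      cig <- c(cig, paste0(intron, "N"))
    }
  }
  list(pos = gpos, cigar = paste(cig, collapse = ""))
}

#' Simulate spliced RNA-seq alignments over the truth loci
#'
#' Emits a valid single-end SAM file: reads drawn uniformly along the target
#' transcript (junction reads carry `N` skip operations whose lengths equal
#' the truth intron lengths) and contiguous reads over the MIRNA precursor
#' region, with per-locus totals proportional to the configured expression.
#'
#' @param truth a `phasilens_truth` object.
#' @param depth positive multiplier on configured read counts.
#' @param seed integer seed.
#' @param path optional output SAM path.
#' @return data.frame of SAM records (qname, flag, rname, pos, mapq, cigar, seq).
#' @export
simulate_rnaseq_alignments <- function(truth, depth = 1, seed = 1L, path = NULL) {
  stopifnot(inherits(truth, "phasilens_truth"))
  if (!is.numeric(depth) || depth <= 0) stop("depth must be > 0", call. = FALSE)
  cfg <- truth$config
  tg <- truth$target_gene
  rl <- cfg$rnaseq_read_len

  with_seed(derive_seed(seed, "rnaseq"), {
    n_t <- round(cfg$rnaseq_target_reads * depth)
    n_m <- round(cfg$rnaseq_mirna_reads * depth)
    tlen <- nchar(tg$transcript)

    recs <- vector("list", n_t + n_m)
    for (i in seq_len(n_t)) {
      t0 <- sample.int(tlen - rl + 1L, 1L)
      m <- transcript_to_genomic_cigar(tg, t0, rl)
      recs[[i]] <- data.frame(
        qname = sprintf("rna%05d", i), flag = sample(c(0L, 16L), 1L),
        rname = tg$seqid, pos = m$pos, mapq = 60L, cigar = m$cigar,
        seq = substr(tg$transcript, t0, t0 + rl - 1L),
        stringsAsFactors = FALSE)
    }
    ml <- truth$mirna_locus
    lo <- max(1L, ml$start - 150L)
    hi <- ml$end + 150L - rl
    for (i in seq_len(n_m)) {
      g0 <- sample(lo:hi, 1L)
      recs[[n_t + i]] <- data.frame(
        qname = sprintf("rna%05d", n_t + i), flag = sample(c(0L, 16L), 1L),
        rname = ml$seqid, pos = g0, mapq = 60L, cigar = paste0(rl, "M"),
        seq = substr(truth$genome[[ml$seqid]], g0, g0 + rl - 1L),
        stringsAsFactors = FALSE)
    }
    sam <- do.call(rbind, recs)
    if (!is.null(path)) write_sam(sam, truth$genome, path)
    sam
  })
}

#' Write SAM records as a text SAM file with header
#'
#' @param sam data.frame as returned by [simulate_rnaseq_alignments()].
#' @param genome named character vector (for `@SQ` lengths).
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_sam <- function(sam, genome, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome), nchar(genome)),
           "@PG\tID:phasilens\tPN:phasilens")
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                  sam$qname, sam$flag, sam$rname, sam$pos, sam$mapq,
                  sam$cigar, sam$seq, strrep("I", nchar(sam$seq)))
  writeLines(c(hdr, body), path)
  invisible(path)
}
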