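# End-to-end orchestration on the bundled synthetic fixture:
# synth -> preprocess -> mirna -> slice -> phase -> tails -> quant,
# each stage consuming only files or objects produced by earlier stages,
# with a machine-readable summary and a manifest of outputs.

#' Run the full pipeline on the synthetic fixture
#'
#' Deterministic for a fixed config and seed. Writes per-stage outputs
#' under numbered subdirectories of `out_dir`, a `summary.tsv` of key
#' results and a `manifest.tsv` of emitted files. An empty preprocessed
#' library (e.g. `min_len` above every read length) propagates as empty
#' downstream tables with a warning, not an error.
#'
#' @param config named list as from [default_config()] or [read_config()].
#' @param out_dir run directory (created; reruns overwrite).
#' @return invisibly, a named list of summary values.
#' @export
run_all <- function(config = default_config(), out_dir = tempfile("phasilens_run_")) {
  cfg <- validate_config(utils::modifyList(default_config(), config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed)
  summary <- list()
  manifest <- character(0)
  emit <- function(df, stage, name) {
    d <- file.path(out_dir, stage)
    dir.create(d, showWarnings = FALSE)
    p <- file.path(d, name)
    write_tsv(df, p)
    manifest <<- c(manifest, file.path(stage, name))
    p
  }

  # -- synth ---------------------------------------------------------------
  stage_log("synth", seed, cfg, "building truth set")
  synth_dir <- file.path(out_dir, "01_synth")
  truth <- build_truth_set(
    list(period = as.integer(cfg$period), n_cycles = as.integer(cfg$n_cycles),
         p_mono_U = cfg$p_mono_U, noise_reads = as.integer(cfg$noise_reads),
         penalty_max = cfg$penalty_max),
    seed = seed, dir = synth_dir)
  reads <- simulate_srna_library(truth, depth = cfg$depth, seed = seed,
                                 adapter = cfg$adapter, dir = synth_dir)
  manifest <- c(manifest, file.path("01_synth",
                                    c("genome.fa", "loci.gff3", "truth.tsv",
                                      "reads.fastq", "labels.tsv")))

  # -- preprocess ----------------------------------------------------------
  stage_log("preprocess", seed, cfg, "trimming/collapsing")
  fastq <- file.path(synth_dir, "reads.fastq")
  if (!file.exists(fastq)) stop("stage preprocess: missing input reads.fastq",
                                call. = FALSE)
  collapsed <- preprocess_library(fastq, cfg$adapter, as.integer(cfg$min_len))
  emit(collapsed, "02_preprocess", "abundance.tsv")
  if (nrow(collapsed)) {
    write_collapsed_fasta(collapsed, file.path(out_dir, "02_preprocess",
                                               "collapsed.fa"))
    manifest <- c(manifest, "02_preprocess/collapsed.fa")
  } else {
    warning("preprocess retained no reads; downstream tables will be empty",
            call. = FALSE)
  }
  summary$n_reads_raw <- nrow(reads)
  summary$n_reads_collapsed <- nrow(collapsed)

  # -- mirna ---------------------------------------------------------------
  stage_log("mirna", seed, cfg, "annotating MIRNA loci")
  if (nrow(collapsed)) {
    ann <- annotate_mirna(collapsed, truth$genome, mincov = cfg$mincov,
                          foldsize = as.integer(cfg$foldsize),
                          max_mismatch = as.integer(cfg$max_mismatch))
  } else {
    ann <- list(report = data.frame(), accepted = data.frame(),
                alignments = data.frame())
  }
  emit(ann$report, "03_mirna", "mirna_report.tsv")
  write_mirna_gff(if (nrow(ann$accepted)) ann$accepted else
                    data.frame(seqid = character(0)),
                  file.path(out_dir, "03_mirna", "mirna.gff3"))
  manifest <- c(manifest, "03_mirna/mirna.gff3")
  summary$n_mirna_loci <- nrow(ann$accepted)
  mature <- if (nrow(ann$accepted)) ann$accepted$mature_seq[1] else NA_character_
  summary$mirna_mature_seq <- mature

  # -- slice ---------------------------------------------------------------
  stage_log("slice", seed, cfg, "detecting slice sites")
  tg <- truth$target_gene
  transcripts <- stats::setNames(tg$transcript, paste0(tg$id, ".1"))
  sites <- data.frame()
  t_aln <- data.frame()
  if (nrow(collapsed) && !is.na(mature)) {
    t_aln <- map_reads(collapsed, transcripts,
                       max_mismatch = as.integer(cfg$max_mismatch))
    tp <- build_tplot(t_aln, nchar(transcripts[[1]]), names(transcripts)[1])
    emit(tplot_table(tp), "04_slice", "tplot.tsv")
    sites <- detect_slice_sites(mature, transcripts[[1]], t_aln,
                                penalty_max = cfg$penalty_max,
                                category_max = as.integer(cfg$category_max),
                                transcript_id = names(transcripts)[1])
  }
  emit(sites, "04_slice", "slice_sites.tsv")
  summary$n_slice_sites <- nrow(sites)
  summary$slice_position <- if (nrow(sites)) sites$slice_position[1] else NA
  summary$slice_category <- if (nrow(sites)) sites$category[1] else NA

  # -- phase ---------------------------------------------------------------
  stage_log("phase", seed, cfg, "phasing analysis")
  phase <- list(report = data.frame(), reads = NULL)
  if (nrow(sites)) {
    phase <- call_phas(t_aln, anchors = sites$slice_position,
                       score_min = cfg$score_min,
                       period = as.integer(cfg$period),
                       transcript_id = names(transcripts)[1])
  }
  emit(phase$report, "05_phase", "phase_report.tsv")
  if (!is.null(phase$reads)) emit(phase$reads, "05_phase", "registers.tsv")
  best <- if (nrow(phase$report)) phase$report[phase$report$best, ][1, ] else NULL
  summary$phase_anchor <- if (!is.null(best)) best$anchor else NA
  summary$phase_score <- if (!is.null(best)) best$score else NA
  summary$phase_k <- if (!is.null(best)) best$k else NA
  summary$phase_verdict <- if (!is.null(best)) best$verdict else NA

  # -- tails ---------------------------------------------------------------
  stage_log("tails", seed, cfg, "classifying 3' tails")
  tails_tab <- data.frame()
  if (nrow(collapsed)) {
    calls <- call_tails(collapsed, truth$genome,
                        max_mismatch = as.integer(cfg$max_mismatch))
    emit(calls, "06_tails", "tail_calls.tsv")
    ml <- truth$mirna_locus
    at_mature <- calls[!is.na(calls$anchor_start) &
                       calls$anchor_seqid == ml$seqid &
                       calls$anchor_start == ml$mature_start &
                       calls$anchor_strand == "+", , drop = FALSE]
    if (nrow(at_mature)) tails_tab <- tail_fraction_report(at_mature)
  }
  emit(tails_tab, "06_tails", "tail_fractions.tsv")
  f22 <- tails_tab$frac_mono_U[tails_tab$length == 22]
  summary$tail_frac_mono_U_22 <- if (length(f22)) f22 else NA
  f21 <- tails_tab$frac_templated[tails_tab$length == 21]
  summary$tail_frac_templated_21 <- if (length(f21)) f21 else NA

  # -- quant ---------------------------------------------------------------
  stage_log("quant", seed, cfg, "expression and junctions")
  quant_dir <- file.path(out_dir, "07_quant")
  dir.create(quant_dir, showWarnings = FALSE)
  sam_path <- file.path(quant_dir, "rnaseq.sam")
  simulate_rnaseq_alignments(truth, depth = cfg$depth, seed = seed,
                             path = sam_path)
  manifest <- c(manifest, "07_quant/rnaseq.sam")
  sam <- read_sam(sam_path)
  ml <- truth$mirna_locus
  loci <- data.frame(locus = c("MIR1", tg$id),
                     seqid = c(ml$seqid, tg$seqid),
                     start = c(ml$start, tg$start),
                     end = c(ml$end, tg$end), stringsAsFactors = FALSE)
  expr <- count_locus_reads(sam, loci)
  emit(expr, "07_quant", "expression.tsv")
  junc <- extract_junctions(sam)
  emit(junc, "07_quant", "junctions.tsv")
  summary$n_junctions <- nrow(junc)
  summary$junction_lengths <- paste(sort(unique(junc$skip_length)),
                                    collapse = ",")

  # -- summary -------------------------------------------------------------
  sm <- data.frame(key = names(summary),
                   value = vapply(summary, function(v)
                     format(v, scientific = FALSE, digits = 15), character(1)),
                   stringsAsFactors = FALSE)
  write_tsv(sm, file.path(out_dir, "summary.tsv"))
  write_tsv(data.frame(file = sort(c(manifest, "summary.tsv"))),
            file.path(out_dir, "manifest.tsv"))
  stage_log("done", seed, cfg, sprintf("outputs in %s", out_dir))
  invisible(summary)
}
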