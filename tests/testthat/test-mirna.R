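test_that("map_reads finds identity and reverse-complement alignments", {
  set.seed(10)
  g <- c(chr = random_dna_str(500))
  read <- substr(g[[1]], 101, 121)
  aln <- map_reads(read, g, max_mismatch = 0L)
  fwd <- aln[aln$strand == "+", ]
  expect_true(any(fwd$start == 101 & fwd$end == 121 & fwd$mismatches == 0))

  rc <- revcomp(read)
  aln2 <- map_reads(rc, g, max_mismatch = 0L)
  rev <- aln2[aln2$strand == "-", ]
  expect_true(any(rev$start == 101 & rev$end == 121))

  expect_error(map_reads(read, character(0)), "genome")
  expect_error(map_reads(read, g, max_mismatch = 2L), "max_mismatch")
})

test_that("map_reads equals the brute-force all-positions scan", {
  set.seed(11)
  g <- c(chr = random_dna_str(2000))
  for (rep_i in 1:8) {
    read <- if (rep_i <= 4) random_dna_str(21)
            else {  # plant a mutated copy to exercise 1-mismatch hits
              x <- substr(g[[1]], 700 + rep_i * 13, 720 + rep_i * 13)
              substr(x, 5, 5) <- setdiff(c("A","C","G","T"), substr(x,5,5))[1]
              x
            }
    got <- map_reads(read, g, max_mismatch = 1L)
    want <- oracle_scan_align(read, g[[1]], max_mm = 1L)
    got <- got[order(got$strand, got$start), c("start", "end", "strand", "mismatches")]
    want <- want[order(want$strand, want$start), ]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, label = paste("read", rep_i))
  }
})

test_that("coverage clustering honours mincov and matches the array oracle", {
  g_len <- c(chr = 1000L)
  stack <- function(n, start, len = 21L) {
    data.frame(sequence = sprintf("s%d", seq_len(n)), count = 1L,
               seqid = "chr", start = start, end = start + len - 1L,
               strand = "+", mismatches = 0L, n_hits = 1L)
  }
  cl <- cluster_by_coverage(stack(20, 100), g_len, mincov = 15)
  expect_equal(nrow(cl), 1L)
  expect_equal(c(cl$start, cl$end), c(100L, 120L))
  expect_equal(nrow(cluster_by_coverage(stack(10, 100), g_len, 15)), 0L)

  set.seed(12)
  aln <- do.call(rbind, lapply(1:40, function(i) {
    s <- sample(1:950, 1)
    data.frame(sequence = sprintf("r%d", i), count = sample(1:10, 1),
               seqid = "chr", start = s, end = s + 20L, strand = "+",
               mismatches = 0L, n_hits = sample(1:2, 1))
  }))
  got <- cluster_by_coverage(aln, g_len, mincov = 8)
  want <- oracle_clusters(aln, 1000L, 8)
  expect_equal(nrow(got), length(want))
  for (i in seq_along(want)) {
    expect_equal(c(got$start[i], got$end[i]), want[[i]])
  }
  # invariant to input order
  perm <- aln[sample(nrow(aln)), ]
  got2 <- cluster_by_coverage(perm, g_len, mincov = 8)
  expect_equal(got2[c("start", "end")], got[c("start", "end")])
})

test_that("fold_window solves small cases and matches exhaustive enumeration", {
  expect_equal(nrow(fold_window("GGGAAACCC")), 3L)
  expect_equal(nrow(fold_window("AAAAAA")), 0L)
  expect_error(fold_window(strrep("A", 400), foldsize = 340L), "foldsize")

  set.seed(13)
  for (i in 1:60) {
    s <- random_dna_str(sample(5:12, 1))
    expect_equal(nrow(fold_window(s)), oracle_max_pairs(s), label = s)
  }
})

test_that("fold_window structures are valid: nested, loop-constrained,
           complementary", {
  set.seed(14)
  for (i in 1:20) {
    s <- random_dna_str(30)
    pr <- fold_window(s)
    if (nrow(pr) == 0) next
    b <- strsplit(s, "")[[1]]
    expect_true(all(oracle_can_pair(b[pr$i], b[pr$j])))
    expect_true(all(pr$j - pr$i > 3))
    expect_false(any(duplicated(c(pr$i, pr$j))))
    # nestedness: no crossing pairs
    for (a in seq_len(nrow(pr))) for (b2 in seq_len(nrow(pr))) {
      if (pr$i[a] < pr$i[b2] && pr$i[b2] < pr$j[a]) {
        expect_lt(pr$j[b2], pr$j[a])
      }
    }
  }
})

test_that("the synthetic hairpin is accepted; removing the star or feeding a
           siRNA-like cluster is rejected with reasons", {
  tr <- fixture_truth0()
  ann <- fixture_ann0()
  expect_equal(nrow(ann$accepted), 1L)
  acc <- ann$accepted
  expect_equal(acc$mature_seq, tr$mirna_locus$mature_seq)
  expect_equal(acc$mature_start, tr$mirna_locus$mature_start)
  expect_equal(acc$star_start, tr$mirna_locus$star_start)
  # mature is a substring of its window
  wseq <- substr(tr$genome[[1]], acc$window_start, acc$window_end)
  expect_true(grepl(acc$mature_seq, wseq, fixed = TRUE))

  # same window without star reads -> no_star
  ml <- tr$mirna_locus
  aln <- ann$alignments
  win <- list(seqid = "chr1", start = acc$window_start, end = acc$window_end)
  wseq_pairs <- fold_window(wseq)
  no_star <- aln[aln$sequence != ml$star_seq, ]
  ev <- evaluate_hairpin(win, no_star, wseq_pairs)
  expect_false(ev$accept)
  expect_equal(ev$reason, "no_star")

  # the phased-siRNA cluster (uniform reads, both strands) is rejected
  phas <- ann$report[ann$report$verdict == "reject", ]
  expect_gte(nrow(phas), 1L)
  expect_true(all(phas$reason %in% c("no_dominant_read", "no_star",
                                     "low_precision")))
})

test_that("MIRNA GFF3 export writes parseable features", {
  ann <- fixture_ann0()
  p <- tempfile(fileext = ".gff3")
  write_mirna_gff(ann$accepted, p)
  gr <- rtracklayer::import(p)
  expect_equal(length(gr), 3L)
  expect_setequal(as.character(gr$type),
                  c("MIRNA_primary_transcript", "miRNA", "miRNA_star"))
})
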