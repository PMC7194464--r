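mk_aln <- function(start, end, strand, count = 1L, seq = NULL) {
  data.frame(sequence = if (is.null(seq)) sprintf("r%d", seq_along(start))
             else seq,
             count = count, seqid = "t", start = start, end = end,
             strand = strand, mismatches = 0L, n_hits = 1L,
             stringsAsFactors = FALSE)
}

test_that("register assignment: anchor, overhang rule, off-register", {
  s <- 112L
  a <- mk_aln(c(112L, 110L, 113L), c(132L, 130L, 133L), c("+", "-", "+"))
  r <- assign_registers(a, s)
  expect_true(r$in_phase[1])            # plus read starting at the anchor
  expect_equal(r$d_label[1], "D1(+)")
  expect_true(r$in_phase[2])            # minus read ending at s + 18
  expect_equal(r$d_label[2], "D1(-)")
  expect_false(r$in_phase[3])           # shifted by +1

  # the antisense partner of cycle k spans s+21k-2 .. s+21k+18
  for (k in 0:3) {
    b <- mk_aln(s + 21L * k - 2L, s + 21L * k + 18L, "-")
    rb <- assign_registers(b, s)
    expect_true(rb$in_phase)
    expect_equal(rb$register, k)
  }
})

test_that("register assignment is translation-equivariant", {
  set.seed(30)
  a <- mk_aln(sample(100:300, 30, TRUE), integer(30),
              sample(c("+", "-"), 30, TRUE))
  a$end <- a$start + 20L
  r1 <- assign_registers(a, 112L)
  b <- a; b$start <- b$start + 37L; b$end <- b$end + 37L
  r2 <- assign_registers(b, 112L + 37L)
  expect_equal(r1$in_phase, r2$in_phase)
  expect_equal(r1$register, r2$register)
})

test_that("phase score: direct formula values and the k_min gate", {
  s <- 100L
  # three cycles of sense reads, total abundance 10, no out-of-phase reads
  a <- mk_aln(s + 21L * (0:2), s + 21L * (0:2) + 20L, rep("+", 3),
              count = c(4L, 3L, 3L))
  ps <- phase_score(a, s)
  expect_equal(ps$k, 3L)
  expect_equal(ps$P, 10)
  expect_equal(ps$U, 0)
  expect_equal(ps$score, log(101), tolerance = 1e-12)

  # k = 2 scores zero regardless of abundance
  a2 <- mk_aln(s + 21L * (0:1), s + 21L * (0:1) + 20L, rep("+", 2),
               count = 50L)
  expect_equal(phase_score(a2, s)$score, 0)
})

test_that("phase score equals an independent formula oracle on random
           windows and is monotone in P and U", {
  set.seed(31)
  for (i in 1:500) {
    n <- sample(5:25, 1)
    starts <- sample(80:320, n, TRUE)
    lens <- sample(18:26, n, TRUE)
    ends <- starts + lens - 1L
    strands <- sample(c("+", "-"), n, TRUE)
    counts <- sample(1:15, n, TRUE)
    a <- mk_aln(starts, ends, strands, counts)
    s <- sample(90:130, 1)
    got <- phase_score(a, s)
    want <- oracle_phase_score(starts, ends, strands, counts, lens, s)
    expect_equal(got$score, want$score, tolerance = 1e-12)
    expect_equal(got$k, want$k)
    expect_equal(got$P, want$P)
    expect_equal(got$U, want$U)
  }

  # monotonicity: more in-phase abundance raises the score; more
  # out-of-phase abundance lowers it
  s <- 100L
  base <- mk_aln(s + 21L * (0:3), s + 21L * (0:3) + 20L, rep("+", 4),
                 count = 5L)
  up <- base; up$count[1] <- 50L
  noise <- rbind(base, mk_aln(s + 5L, s + 25L, "+", count = 30L))
  expect_gt(phase_score(up, s)$score, phase_score(base, s)$score)
  expect_lt(phase_score(noise, s)$score, phase_score(base, s)$score)
})

test_that("scores at anchors s and s+period agree on reads inside both
           windows", {
  s <- 100L; p <- 21L
  a <- mk_aln(s + p * (1:8), s + p * (1:8) + 20L, rep("+", 8), count = 3L)
  ps1 <- phase_score(a, s, window_cycles = 12L)
  ps2 <- phase_score(a, s + p, window_cycles = 12L)
  expect_equal(ps1$P, ps2$P)
  expect_equal(ps1$score, ps2$score, tolerance = 1e-12)
})

test_that("call_phas on the truth set: the truth anchor wins, shifted anchors
           lose, phased reads carry D-labels", {
  tr <- fixture_truth0()
  s <- tr$target_gene$slice_position
  taln <- fixture_taln0()
  anchors <- c(s, s + 1L, s - 1L, s + 5L)
  res <- call_phas(taln, anchors, transcript_id = "TGT1.1")
  rep_ <- res$report
  expect_equal(rep_$anchor[rep_$best], s)
  expect_true(all(rep_$score[rep_$anchor != s] < rep_$score[rep_$anchor == s]))
  expect_equal(rep_$verdict[rep_$anchor == s], "phased")
  expect_equal(rep_$k[rep_$anchor == s], tr$phasing_params$n_cycles)

  # every generated phased read is flagged in phase at the truth anchor
  reads0 <- fixture_reads0()
  phased_seqs <- unique(reads0$sequence[startsWith(reads0$label, "phased")])
  rr <- res$reads
  for (sq in phased_seqs) {
    expect_true(any(rr$sequence == sq & rr$in_phase), label = sq)
  }
})

test_that("uniform random reads stay below the phased verdict threshold", {
  set.seed(33)
  for (rep_i in 1:3) {
    n <- 60
    starts <- sample(1:400, n, TRUE)
    a <- mk_aln(starts, starts + 20L, sample(c("+", "-"), n, TRUE),
                count = sample(1:3, n, TRUE))
    res <- call_phas(a, anchors = sample(50:200, 5))
    expect_true(all(res$report$score < 4))
  }
})

test_that("empty anchor set yields an empty report", {
  res <- call_phas(mk_aln(100L, 120L, "+"), anchors = integer(0))
  expect_equal(nrow(res$report), 0L)
  expect_null(res$reads)
})

test_that("alignment rendering shows reads under the transcript", {
  tr <- fixture_truth0()
  res <- call_phas(fixture_taln0(), tr$target_gene$slice_position)
  lines <- render_phasing_alignment(tr$target_gene$transcript, res$reads,
                                    from = 100L, to = 340L)
  expect_gt(length(lines), 5)
  expect_true(any(grepl("D1\\(\\+\\)", lines)))
})
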