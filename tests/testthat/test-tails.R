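test_that("tail classification covers the four classes and the anchor guard", {
  set.seed(40)
  g <- c(chr = paste0(random_dna_str(60), "ACGTACGTACGTACGTACGTA",
                      "C", random_dna_str(40)))
  core <- substr(g[[1]], 61, 81)    # 21-nt templated core, next base C

  expect_equal(classify_tail(core, g, "chr", 61L)$class,
               if (substr(core, 21, 21) == "T") "ambiguous" else "templated")
  # templated 22-mer (core + genomic C)
  expect_equal(classify_tail(paste0(core, "C"), g, "chr", 61L)$class,
               "templated")
  # non-templated mono-U: final T where the genome has C
  tc <- classify_tail(paste0(core, "T"), g, "chr", 61L)
  expect_equal(tc$class, "mono_U")
  expect_equal(tc$templated_prefix_len, 21L)
  expect_equal(tc$tail, "T")
  # non-T tail
  expect_equal(classify_tail(paste0(core, "G"), g, "chr", 61L)$class,
               "other_tail")
  # two-base tail
  expect_equal(classify_tail(paste0(core, "TT"), g, "chr", 61L)$class,
               "other_tail")
  # templated read ending in T where the genome also has T: ambiguous
  g2 <- c(chr = paste0(random_dna_str(30), "ACGTACGTACGTACGTACG", "TT",
                       random_dna_str(30)))
  read2 <- substr(g2[[1]], 31, 51)
  expect_equal(substr(read2, 21, 21), "T")
  expect_equal(classify_tail(read2, g2, "chr", 31L)$class, "ambiguous")
  # templated prefix below 18 nt is unanchored
  bad <- paste0(substr(core, 1, 10), random_dna_str(11))
  expect_equal(classify_tail(bad, g, "chr", 61L)$class, "unanchored")
})

test_that("fraction report: arithmetic, empty classes, partition", {
  calls <- data.frame(
    sequence = c("a", "b", "c", "d"), length = c(22L, 22L, 21L, 22L),
    count = c(93L, 7L, 50L, 10L),
    class = c("mono_U", "templated", "templated", "ambiguous"),
    templated_prefix_len = c(21L, 22L, 21L, 21L), tail = c("T", "", "", "T"),
    stringsAsFactors = FALSE)
  rep_ <- tail_fraction_report(calls)
  r22 <- rep_[rep_$length == 22, ]
  expect_equal(r22$frac_mono_U, 0.93)
  expect_equal(r22$frac_templated, 0.07)
  expect_equal(r22$frac_ambiguous, 10 / 110)
  # fractions sum to 1 over the unambiguous denominator
  expect_equal(r22$frac_mono_U + r22$frac_templated + r22$frac_other_tail, 1)
  # absent class -> NA, not zero
  rep20 <- tail_fraction_report(calls, length_classes = 20L)
  expect_true(is.na(rep20$frac_mono_U))
  # shares sum to 1 over reported classes
  expect_equal(sum(rep_$share), 1)
})

test_that("fractions equal a brute-force weighted tally on random call sets", {
  set.seed(41)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    calls <- data.frame(
      sequence = sprintf("s%d", 1:n), length = sample(20:23, n, TRUE),
      count = sample(1:50, n, TRUE),
      class = sample(c("templated", "mono_U", "other_tail", "ambiguous"),
                     n, TRUE),
      stringsAsFactors = FALSE)
    rep_ <- tail_fraction_report(calls)
    for (L in unique(calls$length)) {
      cl <- calls[calls$length == L, ]
      denom <- sum(cl$count[cl$class != "ambiguous"])
      got <- rep_[rep_$length == L, ]
      if (denom == 0) {
        expect_true(is.na(got$frac_mono_U))
      } else {
        expect_equal(got$frac_mono_U, sum(cl$count[cl$class == "mono_U"]) / denom)
        expect_equal(got$frac_templated,
                     sum(cl$count[cl$class == "templated"]) / denom)
      }
    }
  }
})

test_that("call_tails on the truth set recovers the generated tail structure", {
  tr <- fixture_truth0()
  calls <- call_tails(fixture_collapsed0(), tr$genome)
  ml <- tr$mirna_locus
  at_mature <- calls[!is.na(calls$anchor_start) &
                     calls$anchor_start == ml$mature_start &
                     calls$anchor_strand == "+", ]
  expect_equal(sort(unique(at_mature$length)), c(21L, 22L))
  rep_ <- tail_fraction_report(at_mature)
  expect_equal(rep_$frac_templated[rep_$length == 21], 1)
  # the 22-nt species splits mono_U vs templated per the generative draw
  reads0 <- fixture_reads0()
  n_u <- sum(reads0$label == "mirna_tailed")
  n22 <- sum(nchar(reads0$sequence) == 22 &
             startsWith(reads0$label, "mirna"))
  expect_equal(rep_$frac_mono_U[rep_$length == 22], n_u / n22)
})

test_that("p_mono_U = 0 yields a zero mono-U fraction", {
  tr <- build_truth_set(list(p_mono_U = 0, noise_reads = 0L), seed = 6L)
  rd <- simulate_srna_library(tr, seed = 6L)
  calls <- call_tails(collapse_reads(rd$sequence), tr$genome)
  rep_ <- tail_fraction_report(calls)
  f22 <- rep_$frac_mono_U[rep_$length == 22]
  expect_equal(f22, 0)
})
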