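# Shared fixtures, built once per test run and cached. The noise-free
# dataset keeps mapping and folding fast; heavier noisy runs live only in
# the tests that need them.

.fix <- new.env(parent = emptyenv())

fixture_truth <- function() {
  if (is.null(.fix$truth)) .fix$truth <- build_truth_set(seed = 42L)
  .fix$truth
}

fixture_reads0 <- function() {   # noise-free read set, seed 42
  if (is.null(.fix$reads0)) {
    .fix$truth0 <- build_truth_set(list(noise_reads = 0L), seed = 42L)
    .fix$reads0 <- simulate_srna_library(.fix$truth0, seed = 42L)
  }
  .fix$reads0
}

fixture_truth0 <- function() { fixture_reads0(); .fix$truth0 }

fixture_collapsed0 <- function() {
  if (is.null(.fix$collapsed0)) {
    .fix$collapsed0 <- rpm_normalize(collapse_reads(fixture_reads0()$sequence))
  }
  .fix$collapsed0
}

fixture_ann0 <- function() {     # MIRNA annotation on the noise-free set
  if (is.null(.fix$ann0)) {
    .fix$ann0 <- annotate_mirna(fixture_collapsed0(), fixture_truth0()$genome)
  }
  .fix$ann0
}

fixture_taln0 <- function() {    # transcript alignments, noise-free set
  if (is.null(.fix$taln0)) {
    tr <- fixture_truth0()
    .fix$taln0 <- map_reads(fixture_collapsed0(),
                            c(TGT1.1 = tr$target_gene$transcript))
  }
  .fix$taln0
}
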