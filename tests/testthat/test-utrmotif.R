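test_that("scan_window honors the half-open window and counts overlaps", {
  # overlap convention
  expect_identical(scan_window("ATATAT", "ATAT", c(0, 200)), c(0L, 2L))
  # start at 190 inside window [0,200) is reported even though the match
  # extends past 200; start at exactly 200 is not
  seq1 <- paste0(strrep("C", 190), "ATGCATGCAT", strrep("C", 50))
  expect_identical(scan_window(seq1, "ATGCATGCAT", c(0, 200)), 190L)
  seq2 <- paste0(strrep("C", 200), "ATGCATGCAT", strrep("C", 50))
  expect_length(scan_window(seq2, "ATGCATGCAT", c(0, 200)), 0)
  # IUPAC degeneracy in the motif
  expect_identical(scan_window("AAGT", "ARGT", c(0, 10)), 0L)
  expect_error(scan_window("ACQT", "ACGT"), "non-IUPAC")
  expect_error(scan_window("ACGT", ""), "non-empty")
})

test_that("hypergeometric enrichment equals the exhaustive pmf-sum oracle", {
  # N=20, K=5, n=8, k=4 constructed explicitly: universe sequences with or
  # without the motif in the window
  motif <- "ATGCATGCAT"
  with_m <- paste0("CC", motif, strrep("G", 138))
  without <- strrep("GC", 75)
  ids <- paste0("u", 1:20)
  seqs <- setNames(rep(without, 20), ids)
  seqs[c(1:4, 10)] <- with_m           # K = 5 carriers
  targets <- ids[c(1:4, 5:8)]          # k = 4 of n = 8
  enr <- enrich_motif(targets, ids, seqs, motif)
  expect_equal(enr$N, 20)
  expect_equal(enr$K, 5)
  expect_equal(enr$n, 8)
  expect_equal(enr$k, 4)
  expect_equal(enr$enrichment, 2.0)
  expect_equal(enr$p_hg, oracle_hg_tail(4, 5, 8, 20), tolerance = 1e-12)

  # saturated case: every gene a carrier
  all_m <- setNames(rep(with_m, 6), paste0("s", 1:6))
  sat <- enrich_motif(names(all_m)[1:3], names(all_m), all_m, motif)
  expect_equal(sat$enrichment, 1)
  expect_equal(sat$p_hg, 1)
  # no-signal case
  none <- enrich_motif(ids[6:9], ids, setNames(rep(without, 20), ids),
                       motif)
  expect_equal(none$k, 0)
  expect_equal(none$enrichment, 0)
  expect_equal(none$p_hg, 1)
})

test_that("p_hg matches stats-free oracle across random count configurations", {
  set.seed(40)
  for (i in 1:25) {
    N <- sample(5:200, 1)
    K <- sample(0:N, 1)
    n <- sample(1:N, 1)
    k_max <- min(n, K)
    k <- if (k_max == 0) 0 else sample(0:k_max, 1)
    p_pkg <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    p_oracle <- if (k == 0) 1 else oracle_hg_tail(k, K, n, N)
    expect_equal(p_pkg, p_oracle, tolerance = 1e-12)
  }
})

test_that("enrichment ignores gene order and sequence outside the window", {
  motif <- "ATGCATGCAT"
  ids <- paste0("u", 1:12)
  base <- strrep("GC", 120)
  seqs <- setNames(rep(base, 12), ids)
  seqs[1:3] <- paste0("AA", motif, strrep("GC", 114))
  targets <- ids[1:4]
  e1 <- enrich_motif(targets, ids, seqs, motif)
  e2 <- enrich_motif(rev(targets), rev(ids), seqs, motif)
  expect_equal(e1$p_hg, e2$p_hg)
  expect_equal(e1$k, e2$k)
  # planting the motif beyond the window changes nothing
  seqs2 <- seqs
  seqs2[5] <- paste0(strrep("GC", 110), motif, "GCGC")
  e3 <- enrich_motif(targets, ids, seqs2, motif)
  expect_equal(e3$K, e1$K)
})

test_that("discovery recovers a planted 10-mer at rank one", {
  motif <- "ATGCATGCAT"
  u <- gen_utrs(50, 500, motif, plant_rate = 0.8, seed = 7)
  disc <- discover_motifs(u$targets, u$universe, u$utrs)
  expect_identical(disc$motif[1], motif)
  expect_lt(disc$p_adj[1], 0.05)
  # adjusted p dominates raw p
  expect_true(all(disc$p_adj >= disc$p_hg - 1e-15))
  expect_error(discover_motifs(c("target_0001", "target_0001"),
                               u$universe, u$utrs), "duplicate")
})

test_that("discovery on unplanted targets finds nothing convincing", {
  u <- gen_utrs(50, 500, "ATGCATGCAT", plant_rate = 0, seed = 33)
  disc <- discover_motifs(u$targets, u$universe, u$utrs)
  if (nrow(disc) > 0) expect_gt(min(disc$p_adj), 0.05)
})

test_that("bias diagnostics behave at their calibration points", {
  motif <- "ATGCATGCAT"
  u <- gen_utrs(40, 200, motif, plant_rate = 0.9, seed = 13)
  rep_bias <- bias_diagnostics(u$targets, u$universe, u$utrs, motif)
  # same generator for targets and background: no GC or length signal
  expect_gt(rep_bias$gc_test$p, 0.01)
  expect_gt(rep_bias$length_test$p, 0.01)
  expect_true(rep_bias$strand_bias$p <= 1)

  # palindromic motif: sense and antisense counts equal, binomial p = 1
  pal <- "ACGCGT"  # reverse complement of itself
  ids <- paste0("p", 1:6)
  seqs <- setNames(rep(paste0(strrep("A", 20), pal, strrep("A", 20)), 6),
                   ids)
  rep_pal <- bias_diagnostics(ids[1:3], ids, seqs, pal)
  expect_equal(rep_pal$strand_bias$sense, rep_pal$strand_bias$antisense)
  expect_equal(rep_pal$strand_bias$p, 1)

  # all matches at one offset: localization p ~ 0
  many <- setNames(rep(paste0(strrep("C", 30), "ATGCATGCAT",
                              strrep("C", 110)), 10),
                   paste0("m", 1:10))
  rep_loc <- bias_diagnostics(names(many), names(many), many,
                              "ATGCATGCAT")
  expect_lt(rep_loc$localization$p, 1e-4)

  # fewer than 5 matches: localization NA with a reason
  few <- setNames(c(paste0("AA", "ATGCATGCAT", strrep("C", 30)),
                    strrep("G", 42)), c("f1", "f2"))
  rep_few <- bias_diagnostics(c("f1", "f2"), c("f1", "f2"), few,
                              "ATGCATGCAT")
  expect_true(is.na(rep_few$localization$p))
  expect_match(rep_few$localization$reason, "need >= 5")
})

test_that("PWM comparison finds identity, offsets and degenerate columns", {
  set.seed(55)
  raw <- matrix(runif(4 * 8, 0.05, 1), 4, 8,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm <- sweep(raw, 2, colSums(raw), "/")
  self <- compare_pwm(pwm, pwm)
  expect_equal(self$score, 1, tolerance = 1e-12)
  expect_identical(self$offset, 0L)
  # a shifted copy is found at the planted offset
  shifted <- pwm[, 3:8]
  hit <- compare_pwm(shifted, pwm)
  expect_equal(hit$score, 1, tolerance = 1e-12)
  expect_equal(hit$offset, 2)
  # column-shuffled copy scores below self-comparison
  shuf <- pwm[, sample(ncol(pwm))]
  expect_lt(compare_pwm(shuf, pwm)$score, 1)
  # uniform columns contribute zero
  unif <- matrix(0.25, 4, 5, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_equal(compare_pwm(unif, pwm)$score, 0, tolerance = 1e-12)
  expect_error(compare_pwm(pwm * 2, pwm), "sum to 1")
})

test_that("pwm_from_sequences and the PWM TSV round-trip agree", {
  seqs <- c("ACGT", "ACGT", "ACTT")
  pwm <- pwm_from_sequences(seqs)
  expect_equal(colSums(pwm), rep(1, 4), tolerance = 1e-12)
  expect_equal(unname(pwm["T", 3]), 1 / 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pwm(pwm, path)
  expect_equal(read_pwm(path), pwm, tolerance = 1e-12)
})
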