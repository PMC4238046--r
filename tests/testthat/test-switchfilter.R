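test_that("partition reproduces the brute-force rule on hand-built inputs", {
  genes <- paste0("g", 1:12)
  sig_tl <- c(rep(TRUE, 6), rep(FALSE, 6))
  sig_tr <- rep(c(TRUE, FALSE), 6)
  tl <- make_diff_result(genes, z = ifelse(sig_tl, 2, 0.1),
                         significant = sig_tl)
  tr <- make_diff_result(genes, z = ifelse(sig_tr, 2, 0.1),
                         significant = sig_tr, compartment = "TR")
  part <- partition_switch(tl, tr)
  want <- oracle_partition(genes, sig_tl, sig_tr)
  got <- setNames(part$table$label, part$table$gene_id)
  expect_identical(got, want)
  # disjoint cover
  expect_equal(sum(part$counts), 12)
  expect_identical(sort(unlist(part$sets, use.names = FALSE)), sort(genes))
})

test_that("partition extremes and symmetry behave", {
  genes <- paste0("g", 1:5)
  all_sig <- make_diff_result(genes, z = 2, significant = rep(TRUE, 5))
  none_sig <- make_diff_result(genes, z = 0.1,
                               significant = rep(FALSE, 5),
                               compartment = "TR")
  part <- partition_switch(all_sig, none_sig)
  expect_identical(unname(part$counts["exclusive_tl"]), 5L)
  # swapping TL and TR swaps the exclusive sets exactly
  rev_part <- partition_switch(none_sig, all_sig)
  expect_identical(rev_part$sets$exclusive_tr, part$sets$exclusive_tl)
  expect_identical(rev_part$sets$exclusive_tl, part$sets$exclusive_tr)
  # significant in both -> shared regardless of direction (default mode)
  tl <- make_diff_result("g1", z = 2, significant = TRUE)
  tr <- make_diff_result("g1", z = -2, significant = TRUE,
                         compartment = "TR")
  expect_identical(partition_switch(tl, tr)$table$label, "shared")
  # direction-matched mode keeps opposite-direction genes exclusive
  expect_identical(partition_switch(tl, tr,
                                    direction_match = TRUE)$table$label,
                   "exclusive_tl")
})

test_that("detection failures are assigned to null and flagged", {
  genes <- paste0("g", 1:3)
  tl <- make_diff_result(genes, z = 2, significant = c(TRUE, TRUE, TRUE))
  tr <- make_diff_result(genes, z = 0.1, significant = rep(FALSE, 3),
                         det_fail = c(TRUE, FALSE, FALSE),
                         compartment = "TR")
  part <- partition_switch(tl, tr)
  expect_identical(part$table$label, c("null", "exclusive_tl",
                                       "exclusive_tl"))
  expect_identical(part$table$detection_failed, c(TRUE, FALSE, FALSE))
})

test_that("unequal universes intersect with warning; disjoint ones error", {
  tl <- make_diff_result(paste0("g", 1:4), z = 2,
                         significant = rep(TRUE, 4))
  tr <- make_diff_result(paste0("g", 3:6), z = 0.1,
                         significant = rep(FALSE, 4), compartment = "TR")
  expect_warning(part <- partition_switch(tl, tr), "universes differ")
  expect_identical(part$table$gene_id, c("g3", "g4"))
  tr2 <- make_diff_result(paste0("h", 1:4), z = 0.1,
                          significant = rep(FALSE, 4), compartment = "TR")
  expect_error(partition_switch(tl, tr2), "disjoint")
})

test_that("venn counts are consistent and conserve the universe", {
  genes <- paste0("g", 1:10)
  sig_tl <- c(rep(TRUE, 5), rep(FALSE, 5))         # 3 excl TL + 2 shared
  sig_tr <- c(rep(FALSE, 3), rep(TRUE, 3), rep(FALSE, 4))
  tl <- make_diff_result(genes, z = ifelse(sig_tl, 2, 0.1),
                         significant = sig_tl)
  tr <- make_diff_result(genes, z = ifelse(sig_tr, 2, 0.1),
                         significant = sig_tr, compartment = "TR")
  vc <- venn_counts(partition_switch(tl, tr))
  expect_identical(vc$venn,
                   list(tl_only = 3L, tr_only = 1L, overlap = 2L,
                        outside = 4L))
  expect_equal(Reduce(`+`, vc$counts), vc$universe_size)
  # empty significance everywhere -> all mass in null
  none <- make_diff_result(genes, z = 0.1, significant = rep(FALSE, 10))
  none_tr <- make_diff_result(genes, z = 0.1,
                              significant = rep(FALSE, 10),
                              compartment = "TR")
  vc0 <- venn_counts(partition_switch(none, none_tr))
  expect_identical(vc0$venn$tl_only, 0L)
  expect_identical(vc0$venn$overlap, 0L)
})

test_that("top tables rank by |z|, then p, then gene id, and truncate", {
  genes <- paste0("g", 1:6)
  z <- c(3, -3, 2, 2, 1.6, 0.1)
  p <- c(0.01, 0.01, 0.001, 0.01, 0.02, 0.5)
  sig <- c(rep(TRUE, 5), FALSE)
  tl <- make_diff_result(genes, z = z, p = p, significant = sig)
  tr <- make_diff_result(genes, z = 0.1, significant = rep(FALSE, 6),
                         compartment = "TR")
  part <- partition_switch(tl, tr)
  top <- top_table(part, tl, tr, n = 10)
  # |z| ties: g1/g2 by gene id; g3 before g4 by p-value
  expect_identical(top$gene_id, c("g1", "g2", "g3", "g4", "g5"))
  expect_message(top_table(part, tl, tr, n = 50), "only 5")
  expect_identical(nrow(top_table(part, tl, tr, n = 2)), 2L)
})

test_that("planted tl_only genes are recovered into exclusive_tl", {
  sim <- gen_expression(gen_config(n_genes = 2000, effect_size = 3,
                                   seed = 101))
  p <- diff_params(n_permutations = 9)
  tl <- diff_contrast(sim$study, sample_contrast("E1", "EV", "TL"), p)
  tr <- diff_contrast(sim$study, sample_contrast("E1", "EV", "TR"), p)
  part <- partition_switch(tl, tr)
  conf <- switch_confusion(part, sim$truth)
  tl_truth <- sim$truth$gene_id[sim$truth$class == "tl_only"]
  recall <- conf["tl_only", "exclusive_tl"] / length(tl_truth)
  precision <- conf["tl_only", "exclusive_tl"] /
    sum(conf[, "exclusive_tl"])
  expect_gte(recall, 0.8)
  expect_gte(precision, 0.8)
  # planted 'both' genes rarely leak into the exclusive set
  leak <- conf["both", "exclusive_tl"] / sum(conf["both", ])
  expect_lte(leak, 0.1)
})
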