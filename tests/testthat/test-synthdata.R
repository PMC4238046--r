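test_that("generators are deterministic given config and seed", {
  cfg <- gen_config(n_genes = 120, effect_size = 2, seed = 5)
  a <- gen_expression(cfg)
  b <- gen_expression(cfg)
  expect_identical(a, b)
  expect_identical(gen_utrs(10, 20, "ATGCATGCAT", 0.5, seed = 3),
                   gen_utrs(10, 20, "ATGCATGCAT", 0.5, seed = 3))
  expect_identical(gen_fractions(seed = 4), gen_fractions(seed = 4))
  expect_identical(gen_decay(seed = 6), gen_decay(seed = 6))
  # different seeds change the noise
  expect_false(identical(gen_decay(seed = 6), gen_decay(seed = 7)))
  # the generator does not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(gen_expression(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("gen_config validates its invariants", {
  expect_error(gen_config(n_genes = 0), "n_genes")
  expect_error(gen_config(n_reps = 1), "n_reps")
  expect_error(gen_config(class_fractions = c(tl_only = 0.5, tr_only = 0.2,
                                              both = 0.2, null = 0.2)),
               "sum to 1")
  expect_error(gen_config(effect_size = -1), "effect_size")
})

test_that("truth classes follow the configured fractions", {
  cfg <- gen_config(n_genes = 4000, seed = 8)
  sim <- gen_expression(cfg)
  expect_identical(sort(unique(sim$truth$gene_id)),
                   sort(rownames(sim$study$log_intensity)))
  frac <- table(sim$truth$class) / 4000
  for (cls in names(cfg$class_fractions)) {
    expected <- cfg$class_fractions[[cls]]
    se <- sqrt(expected * (1 - expected) / 4000)
    expect_lt(abs(frac[[cls]] - expected), 5 * se)
  }
  # null genes carry no planted direction
  expect_true(all(sim$truth$direction[sim$truth$class == "null"] == "0"))
})

test_that("detection failures appear at the configured rate", {
  cfg <- gen_config(n_genes = 2000, detection_fail_rate = 0.1, seed = 12)
  sim <- gen_expression(cfg)
  rate <- mean(sim$study$detection_p > 0.02)
  expect_lt(abs(rate - 0.1), 0.01)
})

test_that("planted effects realize the requested mean |Z-ratio|", {
  cfg <- gen_config(n_genes = 2000, effect_size = 3, seed = 1)
  sim <- gen_expression(cfg)
  z <- zscore_normalize(sim$study$log_intensity[,
         grepl("_TL_", colnames(sim$study$log_intensity))])
  zr <- z_ratio(z, 4:6, 1:3)  # E1 columns follow EV columns
  tl_genes <- sim$truth$gene_id[sim$truth$class == "tl_only"]
  expect_lt(abs(mean(abs(zr[tl_genes])) - 3), 0.5)
  # tl_only genes carry no transcriptome effect
  ztr <- zscore_normalize(sim$study$log_intensity[,
          grepl("_TR_", colnames(sim$study$log_intensity))])
  zr_tr <- z_ratio(ztr, 4:6, 1:3)
  expect_lt(mean(abs(zr_tr[tl_genes])), 1)
})

test_that("pure-null configuration plants nothing and calls little", {
  cfg <- gen_config(n_genes = 500,
                    class_fractions = c(tl_only = 0, tr_only = 0, both = 0,
                                        null = 1), seed = 2)
  sim <- gen_expression(cfg)
  expect_true(all(sim$truth$class == "null"))
  res <- diff_contrast(sim$study, sample_contrast("E1", "EV", "TL"),
                       diff_params(n_permutations = 9))
  expect_lt(mean(res$table$significant), 0.05)
})

test_that("gen_utrs plants the motif inside the window at the stated rate", {
  motif <- "ATGCATGCAT"
  u1 <- gen_utrs(40, 10, motif, plant_rate = 1, utr_length = 250,
                 seed = 21)
  hits <- vapply(u1$targets, function(g) {
    length(scan_window(as.character(u1$utrs[[g]]), motif, c(0, 200))) > 0
  }, logical(1))
  expect_true(all(hits))
  # plant_rate 0: target match frequency comparable to background
  u0 <- gen_utrs(200, 200, motif, plant_rate = 0, seed = 22)
  n_match <- function(ids) {
    mean(vapply(ids, function(g) {
      length(scan_window(as.character(u0$utrs[[g]]), motif, c(0, 200))) > 0
    }, logical(1)))
  }
  expect_lt(abs(n_match(u0$targets) - n_match(u0$background)), 0.05)
  expect_error(gen_utrs(10, 10, "", 0.5), "motif")
  expect_error(gen_utrs(10, 10, "ATGX", 0.5), "motif")
})

test_that("gen_fractions realizes flat and shifted profiles", {
  flat <- gen_fractions(shape = "uniform", shift = 0, n_reps = 1,
                        ct_noise_sd = 0, seed = 1)
  prof <- normalize_fractions(flat[, c("fraction", "target_ct",
                                       "spike_ct")])
  expect_equal(prof$percent, rep(100 / 11, 11), tolerance = 1e-9)

  base <- gen_fractions(shift = 0, n_reps = 1, ct_noise_sd = 0, seed = 2)
  up <- gen_fractions(shift = 0.15, n_reps = 1, ct_noise_sd = 0, seed = 2)
  h0 <- heavy_share(normalize_fractions(base))
  h1 <- heavy_share(normalize_fractions(up))
  expect_equal(h1 - h0, 15, tolerance = 1e-6)
})

test_that("gen_decay follows the closed-form exponential", {
  exact <- gen_decay(half_life = 2, times = c(0, 2, 4), cv = 0,
                     n_reps = 1, seed = 1)
  expect_equal(exact$abundance, c(1, 0.5, 0.25), tolerance = 1e-12)
  expect_error(gen_decay(half_life = 2, times = c(-1, 0, 2)), "negative")
  expect_error(gen_decay(half_life = 2, times = c(2, 4)), "include 0")
  noisy <- gen_decay(half_life = 4.5, cv = 0.1, n_reps = 3, seed = 11)
  expect_equal(nrow(noisy), 15)
  expect_true(all(noisy$abundance > 0))
})
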