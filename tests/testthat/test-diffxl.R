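test_that("detection filter applies the half/all/any rules", {
  mat <- matrix(2, 4, 6)
  study <- make_toy_study(mat, groups = rep(c("T", "R"), each = 3))
  # g1 detected everywhere, g2 in 2/3 test samples only, g3 in 1/3 test
  # samples, g4 nowhere
  det <- matrix(0.5, 4, 6, dimnames = dimnames(study$detection_p))
  det[1, ] <- 0.001
  det[2, 1:2] <- 0.001
  det[3, 1] <- 0.001
  study$detection_p <- det
  ct <- sample_contrast("T", "R", "TL")
  expect_identical(detection_filter(study, ct), c("g1", "g2"))
  expect_identical(detection_filter(study, ct, rule = "all"), "g1")
  expect_identical(detection_filter(study, ct, rule = "any"),
                   c("g1", "g2", "g3"))
  # all detected / none detected extremes
  study$detection_p[] <- 0.001
  expect_identical(detection_filter(study, ct), paste0("g", 1:4))
  study$detection_p[] <- 0.5
  expect_warning(r <- detection_filter(study, ct), "no genes")
  expect_length(r, 0)
})

test_that("Z-score transformation matches its definition and identities", {
  # symmetric three-point case with population SD
  m <- matrix(c(1, 2, 3), 3, 1, dimnames = list(letters[1:3], "s"))
  z <- zscore_normalize(m)
  expect_equal(unname(z[, 1]), c(-1, 0, 1) * sqrt(3 / 2),
               tolerance = 1e-12)

  set.seed(5)
  m <- matrix(rnorm(60, 2, 0.4), 12, 5,
              dimnames = list(paste0("g", 1:12), paste0("s", 1:5)))
  z <- zscore_normalize(m)
  expect_equal(unname(colMeans(z)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, oracle_pop_sd)), rep(1, 5),
               tolerance = 1e-12)
  # affine invariance per column
  m2 <- m
  m2[, 3] <- 2.5 * m[, 3] + 7
  expect_equal(zscore_normalize(m2)[, 3], z[, 3], tolerance = 1e-12)
  # zero-SD column names the sample
  m2[, 4] <- 1
  expect_error(zscore_normalize(m2), "s4")
})

test_that("Z-ratio matches the brute-force oracle and its symmetries", {
  set.seed(11)
  m <- matrix(rnorm(20, 2, 0.3), 5, 4,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  z <- zscore_normalize(m)
  got <- z_ratio(z, 1:2, 3:4)
  expect_equal(unname(got), unname(oracle_zratio(m, 1:2, 3:4)),
               tolerance = 1e-12)
  # antisymmetry under contrast reversal
  expect_equal(z_ratio(z, 3:4, 1:2), -got, tolerance = 1e-12)
  # identical groups guard to zero with warning
  z2 <- cbind(z[, 1:2], z[, 1:2])
  expect_warning(g0 <- z_ratio(z2, 1:2, 3:4), "zero")
  expect_equal(unname(g0), rep(0, 5))
  expect_error(z_ratio(z, 1, 2:4), ">= 2")
})

test_that("gene p-values equal the textbook t-distribution tail", {
  set.seed(3)
  m <- matrix(rnorm(36, 0, 1), 6, 6)
  rownames(m) <- paste0("g", 1:6)
  p <- gene_pvalues(m, 1:3, 4:6)
  for (i in 1:6) {
    expect_equal(unname(p[i]), oracle_t_p(m[i, 1:3], m[i, 4:6]),
                 tolerance = 1e-12)
  }
  # identical group values guard to p = 1 with a flag
  m[1, ] <- 5
  p <- gene_pvalues(m, 1:3, 4:6)
  expect_equal(unname(p[1]), 1)
  expect_true(attr(p, "zero_variance")[1])
  # near-perfect separation drives p toward 0
  m2 <- rbind(g = c(0, 1e-9, -1e-9, 1, 1 + 1e-9, 1 - 1e-9),
              h = rnorm(6))
  expect_lt(gene_pvalues(m2, 1:3, 4:6)[1], 1e-10)
  # Welch agrees with stats::t.test
  w <- gene_pvalues(m2, 1:3, 4:6, welch = TRUE)
  expect_equal(unname(w[2]),
               t.test(m2[2, 1:3], m2[2, 4:6])$p.value, tolerance = 1e-12)
})

test_that("variance exclusion flags high-variance genes at the quantile", {
  set.seed(21)
  z <- matrix(rnorm(600, 0, 1), 100, 6)
  rownames(z) <- paste0("g", 1:100)
  z[7, 1:3] <- z[7, 1:3] * 10
  z[7, 4:6] <- z[7, 4:6] * 10
  excl <- variance_exclusion(z, 1:3, 4:6)
  expect_true(excl["g7"])
  expect_equal(sum(excl), 5)  # 95th-percentile rule on 100 genes
  expect_false(any(variance_exclusion(z, 1:3, 4:6, threshold = 1)))
  anov <- variance_exclusion(z, 1:3, 4:6, method = "anova",
                             threshold = 0.01)
  expect_type(anov, "logical")
  expect_named(anov, rownames(z))
})

test_that("empirical FDR is monotone and small for dominant effects", {
  set.seed(9)
  m <- matrix(rnorm(1200, 2, 0.2), 200, 6)
  rownames(m) <- paste0("g", 1:200)
  m[1:10, 1:3] <- m[1:10, 1:3] + 3   # overwhelming planted effects
  z <- zscore_normalize(m)
  expect_warning(fdr <- empirical_fdr(z, 1:3, 4:6, n_permutations = 1000),
                 "distinct")
  zr <- abs(z_ratio(z, 1:3, 4:6))
  # monotone non-increasing in |z|
  ord <- order(zr, decreasing = TRUE)
  expect_true(all(diff(fdr[ord]) >= -1e-12))
  expect_equal(unname(fdr[ord[1]]), min(fdr))
  expect_lt(max(fdr[1:10]), 0.05)
  expect_true(all(fdr >= 0 & fdr <= 1))
})

test_that("significance calls apply the three gates and boundaries", {
  params <- diff_params()
  tab <- data.frame(
    gene_id = c("a", "b", "c", "d", "e"),
    z_ratio = c(1.6, 1.6, -1.5, 1.49, -2),
    p_value = c(0.01, 0.2, 0.05 - 1e-9, 0.01, 0.01),
    fdr = c(0.2, 0.2, 0.3, 0.1, 0.31),
    excluded_by_detection = FALSE,
    excluded_by_variance = c(FALSE, FALSE, FALSE, FALSE, FALSE))
  out <- call_significant(tab, params)
  expect_identical(out$significant, c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_identical(out$direction, c("up", "none", "down", "none", "none"))
  # excluded genes can never be significant
  tab$excluded_by_variance <- TRUE
  expect_false(any(call_significant(tab, params)$significant))
})

test_that("diff_contrast matches a full brute-force recomputation on a toy study", {
  set.seed(17)
  mat <- matrix(rnorm(30, 2, 0.25), 5, 6,
                dimnames = list(paste0("g", 1:5), NULL))
  study <- make_toy_study(mat, groups = rep(c("T", "R"), each = 3))
  res <- diff_contrast(study, sample_contrast("T", "R", "TL"),
                       diff_params(n_permutations = 9,
                                   variance_method = "none"))
  tab <- res$table
  expect_equal(tab$z_ratio, unname(oracle_zratio(mat, 1:3, 4:6)),
               tolerance = 1e-12)
  z <- oracle_zscore(mat)
  for (i in 1:5) {
    expect_equal(tab$p_value[i], oracle_t_p(z[i, 1:3], z[i, 4:6]),
                 tolerance = 1e-12)
  }
  expect_true(all(!tab$excluded_by_detection))
  # significant implies every gate
  sig <- tab$significant
  expect_true(all(abs(tab$z_ratio[sig]) >= 1.5))
  expect_true(all(tab$fdr[sig] <= 0.3))
  expect_true(all(tab$p_value[sig] < 0.05))
})

test_that("diff_contrast is invariant under per-sample affine rescaling", {
  sim <- gen_expression(gen_config(n_genes = 150, seed = 30))
  study <- sim$study
  study2 <- study
  scale <- runif(ncol(study2$log_intensity), 0.5, 2)
  shift <- runif(ncol(study2$log_intensity), -1, 1)
  study2$log_intensity <- sweep(sweep(study2$log_intensity, 2, scale, "*"),
                                2, shift, "+")
  ct <- sample_contrast("E1", "EV", "TL")
  p <- diff_params(n_permutations = 9)
  r1 <- diff_contrast(study, ct, p)
  r2 <- diff_contrast(study2, ct, p)
  expect_equal(r1$table$z_ratio, r2$table$z_ratio, tolerance = 1e-9)
  expect_equal(r1$table$p_value, r2$table$p_value, tolerance = 1e-9)
})

test_that("an empty retained set yields an empty result, not an error", {
  mat <- matrix(rnorm(24, 2, 0.2), 4, 6)
  study <- make_toy_study(mat, groups = rep(c("T", "R"), each = 3),
                          detection = 0.9)
  expect_warning(
    res <- diff_contrast(study, sample_contrast("T", "R", "TL"),
                         diff_params(n_permutations = 9)),
    "no genes")
  expect_true(all(res$table$excluded_by_detection))
  expect_true(all(is.na(res$table$z_ratio)))
  expect_false(any(res$table$significant))
})
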