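# Independent brute-force oracles: deliberately loop-level, step-by-step
# reimplementations of the statistics, kept free of any package internals
# so they can certify the vectorized implementations on small fixtures.

oracle_pop_sd <- function(x) {
  m <- sum(x) / length(x)
  s2 <- 0
  for (v in x) s2 <- s2 + (v - m)^2
  sqrt(s2 / length(x))
}

oracle_zscore <- function(mat) {
  out <- mat
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    m <- mean(col)
    s <- oracle_pop_sd(col)
    for (i in seq_len(nrow(mat))) out[i, j] <- (mat[i, j] - m) / s
  }
  out
}

# Z-ratio per the definition: difference of group-mean Z-scores divided by
# the population SD of those differences across genes.
oracle_zratio <- function(mat, test_cols, ref_cols) {
  z <- oracle_zscore(mat)
  d <- numeric(nrow(mat))
  for (i in seq_len(nrow(mat))) {
    d[i] <- mean(z[i, test_cols]) - mean(z[i, ref_cols])
  }
  denom <- oracle_pop_sd(d)
  d / denom
}

# Two-sample equal-variance two-tailed t-test from the textbook formula.
oracle_t_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  if (sp2 == 0) return(1)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  2 * pt(-abs(tstat), df = n1 + n2 - 2)
}

# Hypergeometric upper tail P[X >= k] by exhaustive pmf summation.
oracle_hg_tail <- function(k, K, n, N) {
  total <- 0
  for (i in seq(k, min(n, K))) {
    total <- total + choose(K, i) * choose(N - K, n - i) / choose(N, n)
  }
  if (k > min(n, K)) total <- 0
  total
}

# Four-way switch partition from two significance vectors.
oracle_partition <- function(genes, sig_tl, sig_tr) {
  out <- character(length(genes))
  for (i in seq_along(genes)) {
    out[i] <- if (sig_tl[i] && sig_tr[i]) "shared"
      else if (sig_tl[i]) "exclusive_tl"
      else if (sig_tr[i]) "exclusive_tr"
      else "null"
  }
  names(out) <- genes
  out
}
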