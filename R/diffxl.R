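# The Z-ratio differential-expression engine.
#
# Pipeline per contrast: detection filter -> per-sample Z-score
# transformation (population SD, retained genes only) -> Z-ratio statistic
# -> per-gene two-sample t-test on Z-scores -> variance exclusion ->
# label-permutation empirical FDR -> significance call at the configured
# thresholds (|Z-ratio| >= 1.5, FDR <= 0.3, p < 0.05 by default).

#' Differential-expression parameters
#'
#' Thresholds and method switches for [diff_contrast()]. Defaults follow the
#' conventional Z-ratio significance recipe for bead-array studies:
#' observations kept at detection p <= 0.02, and a gene called significant
#' when |Z-ratio| >= 1.5, empirical FDR <= 0.3 and two-tailed t-test
#' p < 0.05, provided it was not excluded by detection or variance screens.
#'
#' @param detection_p_max Detection p-value cutoff (observation detected when
#'   p <= this; default 0.02).
#' @param detection_rule How many detected observations keep a gene:
#'   `"half"` (at least half the samples, rounded up, of at least one of the
#'   two contrast groups; default), `"all"` (every sample of both groups), or
#'   `"any"` (any single sample).
#' @param zratio_min Absolute Z-ratio significance gate, inclusive
#'   (default 1.5).
#' @param fdr_max Empirical FDR gate, inclusive (default 0.3).
#' @param p_max t-test p-value gate, exclusive (default 0.05).
#' @param variance_method Variance-exclusion screen: `"within-group-sd"`
#'   (default; exclude genes whose pooled within-group SD of Z-scores
#'   exceeds the `variance_threshold` quantile of all genes), `"anova"`
#'   (one-way ANOVA across replicate batches, exclude at
#'   p < `variance_threshold`), or `"none"`.
#' @param variance_threshold Quantile for `"within-group-sd"` (default 0.95;
#'   1 disables exclusions) or p-value cutoff for `"anova"` (default 0.01 if
#'   unset).
#' @param welch Use Welch's unequal-variance t-test instead of the
#'   equal-variance (pooled) test (default `FALSE`).
#' @param n_permutations Requested label permutations for the empirical FDR
#'   (default 1000); when fewer distinct non-identity label splits exist they
#'   are all used, with a warning.
#' @param seed Seed for the permutation stream (default 1).
#' @return A list of class `diff_params`.
#' @export
diff_params <- function(detection_p_max = 0.02,
                        detection_rule = c("half", "all", "any"),
                        zratio_min = 1.5, fdr_max = 0.3, p_max = 0.05,
                        variance_method = c("within-group-sd", "anova",
                                            "none"),
                        variance_threshold = NULL,
                        welch = FALSE,
                        n_permutations = 1000L, seed = 1L) {
  detection_rule <- match.arg(detection_rule)
  variance_method <- match.arg(variance_method)
  if (is.null(variance_threshold)) {
    variance_threshold <- if (variance_method == "anova") 0.01 else 0.95
  }
  params <- list(
    detection_p_max = assert_number(detection_p_max, "detection_p_max",
                                    min = 0, max = 1, open_min = TRUE),
    detection_rule = detection_rule,
    zratio_min = assert_number(zratio_min, "zratio_min", min = 0,
                               open_min = TRUE),
    fdr_max = assert_number(fdr_max, "fdr_max", min = 0, max = 1,
                            open_min = TRUE),
    p_max = assert_number(p_max, "p_max", min = 0, max = 1, open_min = TRUE),
    variance_method = variance_method,
    variance_threshold = assert_number(variance_threshold,
                                       "variance_threshold", min = 0,
                                       max = 1),
    welch = isTRUE(welch),
    n_permutations = assert_count(n_permutations, "n_permutations"),
    seed = assert_count(seed, "seed", min = 0L)
  )
  class(params) <- "diff_params"
  params
}

#' Detection filter
#'
#' A gene is retained when its detection p-value is at or below
#' `p_max` in enough samples of the contrast: under the default `"half"`
#' rule, in at least half (rounded up) of the samples of at least one of the
#' two groups.
#'
#' @param study An [expression_study()].
#' @param contrast A [sample_contrast()].
#' @param p_max Detection p-value cutoff (default 0.02).
#' @param rule `"half"`, `"all"` or `"any"`; see [diff_params()].
#' @return Character vector of retained gene identifiers (possibly empty,
#'   with a warning).
#' @export
detection_filter <- function(study, contrast, p_max = 0.02,
                             rule = c("half", "all", "any")) {
  rule <- match.arg(rule)
  idx <- contrast_columns(study, contrast)
  det <- study$detection_p
  hits_test <- rowSums(det[, idx$test, drop = FALSE] <= p_max)
  hits_ref <- rowSums(det[, idx$ref, drop = FALSE] <= p_max)
  n_test <- length(idx$test)
  n_ref <- length(idx$ref)
  keep <- switch(rule,
    half = hits_test >= ceiling(n_test / 2) | hits_ref >= ceiling(n_ref / 2),
    all = hits_test == n_test & hits_ref == n_ref,
    any = hits_test + hits_ref >= 1L
  )
  retained <- rownames(det)[keep]
  if (length(retained) == 0L) {
    warning("detection filter retained no genes", call. = FALSE)
  }
  retained
}

#' Per-sample Z-score transformation
#'
#' Standardizes each column (sample) of a log10-intensity matrix to mean 0
#' and population SD 1, computed over the supplied genes only.
#'
#' @param x Numeric gene x sample matrix of log10 intensities, or an
#'   [expression_study()] (its full intensity matrix is used).
#' @param genes Optional gene identifiers to restrict to (the detection-
#'   retained set); default all rows.
#' @return The Z-score matrix for the selected genes.
#' @export
zscore_normalize <- function(x, genes = NULL) {
  if (inherits(x, "expression_study")) x <- x$log_intensity
  stopifnot(is.matrix(x), is.numeric(x))
  if (!is.null(genes)) x <- x[genes, , drop = FALSE]
  mu <- colMeans(x)
  sds <- apply(x, 2L, pop_sd)
  zero <- which(sds == 0 | !is.finite(sds))
  if (length(zero)) {
    stop("zero intensity SD in sample(s): ",
         paste(colnames(x)[zero], collapse = ", "), call. = FALSE)
  }
  sweep(sweep(x, 2L, mu, "-"), 2L, sds, "/")
}

# Z-ratio numerator/denominator core. Returns the per-gene difference of
# group-mean Z-scores, the across-gene population SD of those differences
# (the Z-ratio denominator), and the Z-ratios themselves. A zero denominator
# (e.g. test group identical to reference group) is guarded to all-zero
# Z-ratios with a warning.
zratio_core <- function(zmat, test_idx, ref_idx) {
  d <- rowMeans(zmat[, test_idx, drop = FALSE]) -
    rowMeans(zmat[, ref_idx, drop = FALSE])
  denom <- pop_sd(d)
  if (!is.finite(denom) || denom == 0) {
    warning("Z-ratio denominator is zero; returning all-zero Z-ratios",
            call. = FALSE)
    z <- d * 0
    denom <- 0
  } else {
    z <- d / denom
  }
  list(diff = d, denom = denom, z_ratio = z)
}

#' Z-ratio statistic
#'
#' For each gene, the difference between its mean Z-score in the test group
#' and in the reference group, divided by the population SD of those
#' per-gene differences across all supplied genes. Z-ratios are therefore on
#' a common, dimensionless scale: under a pure null they are approximately
#' standard normal, and swapping the two groups negates every value.
#'
#' @param zmat Z-score matrix (genes x samples), e.g. from
#'   [zscore_normalize()].
#' @param test_idx,ref_idx Column indices (or names) of the test and
#'   reference samples; each group needs >= 2 columns.
#' @return Named numeric vector of per-gene Z-ratios.
#' @export
z_ratio <- function(zmat, test_idx, ref_idx) {
  stopifnot(is.matrix(zmat))
  if (length(test_idx) < 2L || length(ref_idx) < 2L) {
    stop("each group needs >= 2 replicates", call. = FALSE)
  }
  zratio_core(zmat, test_idx, ref_idx)$z_ratio
}

# Row-wise two-sample t-test on Z-scores. Equal-variance (pooled) by
# default; Welch by flag. Zero pooled variance is guarded to p = 1 and
# flagged.
ttest_rows <- function(zmat, test_idx, ref_idx, welch = FALSE) {
  x <- zmat[, test_idx, drop = FALSE]
  y <- zmat[, ref_idx, drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- apply(x, 1L, stats::var)
  v2 <- apply(y, 1L, stats::var)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    se <- sqrt(se2)
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep.int(n1 + n2 - 2, nrow(zmat))
  }
  zero_var <- !is.finite(se) | se == 0
  tstat <- ifelse(zero_var, 0, (m1 - m2) / se)
  p <- ifelse(zero_var, 1, 2 * stats::pt(-abs(tstat), df))
  list(p = p, t = tstat, zero_variance = zero_var,
       mean_test = m1, mean_ref = m2)
}

#' Per-gene t-test p-values on Z-scores
#'
#' Two-sample, two-tailed Student's t-test (equal-variance pooled estimate by
#' default, Welch by flag) applied row-wise to the Z-score matrix. Genes with
#' zero pooled variance are guarded to p = 1 and flagged in the
#' `"zero_variance"` attribute.
#'
#' @inheritParams z_ratio
#' @param welch Use Welch's test (default `FALSE`).
#' @return Named numeric vector of p-values with attribute `zero_variance`.
#' @export
gene_pvalues <- function(zmat, test_idx, ref_idx, welch = FALSE) {
  stopifnot(is.matrix(zmat))
  if (length(test_idx) < 2L || length(ref_idx) < 2L) {
    stop("each group needs >= 2 replicates", call. = FALSE)
  }
  res <- ttest_rows(zmat, test_idx, ref_idx, welch = welch)
  structure(stats::setNames(res$p, rownames(zmat)),
            zero_variance = res$zero_variance)
}

#' Variance-exclusion screen
#'
#' Flags genes whose replicate variability is large enough to distrust their
#' contrast statistics. The default `"within-group-sd"` method excludes genes
#' whose pooled within-group SD of Z-scores strictly exceeds the configured
#' quantile (default 95th percentile) of all genes; a quantile of 1 disables
#' exclusions. The `"anova"` method fits a one-way ANOVA across replicate
#' batches (replicate index as factor, samples of both groups as
#' observations) and excludes genes with p below the threshold.
#'
#' @inheritParams z_ratio
#' @param method `"within-group-sd"`, `"anova"` or `"none"`.
#' @param threshold Quantile (within-group-sd) or p-value cutoff (anova).
#' @return Logical vector, `TRUE` where the gene is excluded.
#' @export
variance_exclusion <- function(zmat, test_idx, ref_idx,
                               method = c("within-group-sd", "anova",
                                          "none"),
                               threshold = NULL) {
  method <- match.arg(method)
  n <- nrow(zmat)
  out <- stats::setNames(rep.int(FALSE, n), rownames(zmat))
  if (method == "none" || n == 0L) return(out)
  if (method == "within-group-sd") {
    threshold <- threshold %||% 0.95
    x <- zmat[, test_idx, drop = FALSE]
    y <- zmat[, ref_idx, drop = FALSE]
    n1 <- ncol(x); n2 <- ncol(y)
    v1 <- apply(x, 1L, stats::var)
    v2 <- apply(y, 1L, stats::var)
    pooled_sd <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
    cut <- stats::quantile(pooled_sd, threshold, names = FALSE, type = 7)
    out[] <- pooled_sd > cut
  } else {
    threshold <- threshold %||% 0.01
    if (length(test_idx) != length(ref_idx)) {
      stop("anova variance exclusion needs equal replicate counts",
           call. = FALSE)
    }
    batch <- factor(c(seq_along(test_idx), seq_along(ref_idx)))
    vals <- zmat[, c(test_idx, ref_idx), drop = FALSE]
    for (i in seq_len(n)) {
      fit <- stats::aov(vals[i, ] ~ batch)
      p <- summary(fit)[[1L]][["Pr(>F)"]][1L]
      out[i] <- is.finite(p) && p < threshold
    }
  }
  out
}

# Enumerate (or sample) distinct non-identity label splits of the contrast
# columns. Columns are taken as c(test, ref); a split is the set of columns
# relabelled "test". When group sizes are equal a split and its complement
# give the same |Z-ratio|s, so only one of each pair is kept. The identity
# (observed) split is never part of the null.
perm_splits <- function(n_test, n_ref, n_perm, seed) {
  n_tot <- n_test + n_ref
  n_all <- choose(n_tot, n_test)
  n_distinct <- if (n_test == n_ref) n_all / 2L else n_all
  n_distinct <- n_distinct - 1L  # drop the identity split
  if (n_distinct < 1L) {
    stop("no non-identity label permutations available", call. = FALSE)
  }
  if (n_distinct <= n_perm) {
    if (n_distinct < n_perm) {
      warning(sprintf(
        "only %d distinct non-identity label splits; using all of them",
        n_distinct), call. = FALSE)
    }
    combos <- utils::combn(n_tot, n_test, simplify = FALSE)
    if (n_test == n_ref) {
      combos <- Filter(function(s) 1L %in% s, combos)
    }
    combos <- Filter(function(s) !identical(s, seq_len(n_test)), combos)
    combos
  } else {
    with_seed(seed, {
      seen <- new.env(parent = emptyenv())
      out <- vector("list", n_perm)
      got <- 0L
      while (got < n_perm) {
        s <- sort(sample.int(n_tot, n_test))
        if (n_test == n_ref && !(1L %in% s)) s <- sort(setdiff(seq_len(n_tot), s))
        if (identical(s, seq_len(n_test))) next
        key <- paste(s, collapse = ",")
        if (!is.null(seen[[key]])) next
        assign(key, TRUE, envir = seen)
        got <- got + 1L
        out[[got]] <- s
      }
      out
    })
  }
}

#' Label-permutation empirical FDR
#'
#' For each gene's observed |Z-ratio| taken as a threshold `t`, the FDR is
#' the permutation-average count of null |Z-ratios| at or above `t`, divided
#' by the observed count at or above `t`, capped at 1. Null Z-ratios come
#' from relabelling the contrast's samples (all distinct non-identity splits
#' when fewer than `n_permutations` exist, otherwise a seeded random
#' subset); permuted group-mean differences are standardized by the observed
#' across-gene SD so null and observed statistics share one scale. Estimates
#' are then monotone-smoothed so that FDR is non-increasing in |Z-ratio|
#' (each gene receives the smallest raw estimate among thresholds at or
#' below its own).
#'
#' @inheritParams z_ratio
#' @param z_ratios Optional precomputed Z-ratios for these columns (computed
#'   if omitted).
#' @param n_permutations Requested number of permutations (default 1000).
#' @param seed Seed for the permutation stream.
#' @return Named numeric vector of FDR values in `[0, 1]`.
#' @export
empirical_fdr <- function(zmat, test_idx, ref_idx, z_ratios = NULL,
                          n_permutations = 1000L, seed = 1L) {
  stopifnot(is.matrix(zmat))
  n_permutations <- assert_count(n_permutations, "n_permutations")
  core <- zratio_core(zmat, test_idx, ref_idx)
  if (is.null(z_ratios)) z_ratios <- core$z_ratio
  denom <- core$denom
  if (denom == 0) {
    return(stats::setNames(rep.int(1, nrow(zmat)), rownames(zmat)))
  }
  cols <- c(test_idx, ref_idx)
  n_test <- length(test_idx)
  splits <- perm_splits(n_test, length(ref_idx), n_permutations, seed)
  sub <- zmat[, cols, drop = FALSE]
  null_abs <- unlist(lapply(splits, function(s) {
    t_cols <- s
    r_cols <- setdiff(seq_along(cols), s)
    d <- rowMeans(sub[, t_cols, drop = FALSE]) -
      rowMeans(sub[, r_cols, drop = FALSE])
    abs(d / denom)
  }), use.names = FALSE)
  n_perm <- length(splits)
  obs_abs <- abs(z_ratios)
  null_sorted <- sort(null_abs)
  obs_sorted <- sort(obs_abs)
  n_null_ge <- length(null_sorted) -
    findInterval(obs_abs, null_sorted, left.open = TRUE)
  n_obs_ge <- length(obs_sorted) -
    findInterval(obs_abs, obs_sorted, left.open = TRUE)
  raw <- pmin(1, (n_null_ge / n_perm) / pmax(n_obs_ge, 1L))
  ord <- order(obs_abs)
  smoothed <- raw
  smoothed[ord] <- cummin(raw[ord])
  stats::setNames(smoothed, rownames(zmat))
}

#' Apply the significance gates to a differential table
#'
#' A gene is significant when |Z-ratio| >= `zratio_min`, FDR <= `fdr_max`,
#' p < `p_max`, and it was excluded by neither the detection nor the
#' variance screen. Direction is the sign of the Z-ratio.
#'
#' @param table Data frame with columns `z_ratio`, `p_value`, `fdr`,
#'   `excluded_by_detection`, `excluded_by_variance`.
#' @param params A [diff_params()] object.
#' @return The table with `significant` (logical) and `direction`
#'   (`"up"`, `"down"`, `"none"`) columns filled in.
#' @export
call_significant <- function(table, params = diff_params()) {
  stopifnot(is.data.frame(table))
  sig <- !is.na(table$z_ratio) &
    abs(table$z_ratio) >= params$zratio_min &
    !is.na(table$fdr) & table$fdr <= params$fdr_max &
    !is.na(table$p_value) & table$p_value < params$p_max &
    !table$excluded_by_detection & !table$excluded_by_variance
  table$significant <- sig
  table$direction <- ifelse(!sig, "none",
                            ifelse(table$z_ratio > 0, "up", "down"))
  table
}

#' Run the full Z-ratio differential analysis for one contrast
#'
#' Applies, in order: the detection filter, per-sample Z-score normalization
#' over retained genes, the Z-ratio statistic, row-wise t-tests, the
#' variance-exclusion screen, the label-permutation empirical FDR, and the
#' significance gates. Genes removed by the detection filter are kept in the
#' output with `NA` statistics and `excluded_by_detection = TRUE`.
#'
#' @param study An [expression_study()].
#' @param contrast A [sample_contrast()].
#' @param params A [diff_params()] object.
#' @return An object of class `diff_result`: a list with `table` (one row
#'   per gene of the study, in study order), `contrast`, `params`, and
#'   `metadata` (method decisions recorded for the run manifest).
#' @export
#' @examples
#' sim <- gen_expression(gen_config(n_genes = 300, seed = 42))
#' res <- diff_contrast(sim$study, sample_contrast("E1", "EV", "TL"),
#'                      diff_params(n_permutations = 50))
#' summary(res)
diff_contrast <- function(study, contrast, params = diff_params()) {
  stopifnot(inherits(study, "expression_study"),
            inherits(contrast, "sample_contrast"),
            inherits(params, "diff_params"))
  idx <- contrast_columns(study, contrast)
  genes <- rownames(study$log_intensity)
  retained <- detection_filter(study, contrast, params$detection_p_max,
                               params$detection_rule)
  tab <- data.frame(
    gene_id = genes,
    mean_z_test = NA_real_, mean_z_ref = NA_real_,
    z_ratio = NA_real_, p_value = NA_real_, fdr = NA_real_,
    excluded_by_detection = !(genes %in% retained),
    excluded_by_variance = FALSE,
    zero_variance = FALSE,
    significant = FALSE, direction = "none",
    stringsAsFactors = FALSE
  )
  rownames(tab) <- genes
  if (length(retained) > 0L) {
    zmat <- zscore_normalize(study$log_intensity[, c(idx$test, idx$ref),
                                                 drop = FALSE],
                             genes = retained)
    t_cols <- seq_along(idx$test)
    r_cols <- length(idx$test) + seq_along(idx$ref)
    zr <- zratio_core(zmat, t_cols, r_cols)
    tt <- ttest_rows(zmat, t_cols, r_cols, welch = params$welch)
    excl_var <- variance_exclusion(zmat, t_cols, r_cols,
                                   method = params$variance_method,
                                   threshold = params$variance_threshold)
    fdr <- empirical_fdr(zmat, t_cols, r_cols, z_ratios = zr$z_ratio,
                         n_permutations = params$n_permutations,
                         seed = params$seed)
    tab[retained, "mean_z_test"] <- tt$mean_test
    tab[retained, "mean_z_ref"] <- tt$mean_ref
    tab[retained, "z_ratio"] <- zr$z_ratio
    tab[retained, "p_value"] <- tt$p
    tab[retained, "fdr"] <- fdr
    tab[retained, "zero_variance"] <- tt$zero_variance
    tab[retained, "excluded_by_variance"] <- excl_var
  }
  tab <- call_significant(tab, params)
  structure(list(
    table = tab,
    contrast = contrast,
    params = params,
    metadata = list(
      n_retained = length(retained),
      n_test = length(idx$test), n_ref = length(idx$ref),
      zscore_sd = "population",
      log_base = "log10",
      t_test = if (params$welch) "welch" else "equal-variance",
      fdr_method = "label-permutation tail-area FDR, monotone-smoothed",
      boundary = "|z_ratio| >= zratio_min, fdr <= fdr_max, p < p_max"
    )
  ), class = "diff_result")
}

#' @export
print.diff_result <- function(x, ...) {
  cat(sprintf("Z-ratio differential result: %s vs %s [%s]\n",
              x$contrast$test, x$contrast$reference,
              x$contrast$compartment))
  cat(sprintf("  %d genes, %d retained by detection, %d significant (%d up, %d down)\n",
              nrow(x$table), x$metadata$n_retained,
              sum(x$table$significant),
              sum(x$table$direction == "up"),
              sum(x$table$direction == "down")))
  invisible(x)
}

#' @method summary diff_result
#' @export
summary.diff_result <- function(object, ...) {
  tab <- object$table
  out <- list(
    contrast = format(object$contrast),
    n_genes = nrow(tab),
    n_retained = object$metadata$n_retained,
    n_excluded_variance = sum(tab$excluded_by_variance),
    n_significant = sum(tab$significant),
    n_up = sum(tab$direction == "up"),
    n_down = sum(tab$direction == "down")
  )
  class(out) <- "summary.diff_result"
  out
}

#' @method print summary.diff_result
#' @export
print.summary.diff_result <- function(x, ...) {
  cat("Contrast:            ", x$contrast, "\n")
  cat("Genes:               ", x$n_genes, "\n")
  cat("Retained (detection):", x$n_retained, "\n")
  cat("Excluded (variance): ", x$n_excluded_variance, "\n")
  cat("Significant:         ", x$n_significant,
      sprintf("(%d up, %d down)", x$n_up, x$n_down), "\n")
  invisible(x)
}

#' @method as.data.frame diff_result
#' @export
as.data.frame.diff_result <- function(x, ...) x$table

#' Write a differential result as a TSV table plus JSON metadata sidecar
#'
#' @param result A [diff_contrast()] result.
#' @param path Output TSV path; the sidecar is written next to it with a
#'   `.meta.json` suffix.
#' @return Invisibly, the two paths.
#' @export
write_diff_result <- function(result, path) {
  stopifnot(inherits(result, "diff_result"))
  write_tsv(result$table, path)
  meta <- c(result$metadata,
            list(contrast = unclass(result$contrast),
                 params = unclass(result$params)))
  meta_path <- paste0(sub("\\.tsv$", "", path), ".meta.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(path, meta_path))
}
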