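# Small in-code fixtures shared across test files.

# A minimal two-group, one-compartment study built from an explicit matrix.
make_toy_study <- function(mat, compartment = "TL",
                           groups = c("T", "T", "R", "R"),
                           detection = 0.001) {
  n_per <- table(groups)
  reps <- unlist(lapply(n_per[unique(groups)], seq_len), use.names = FALSE)
  reps <- ave(seq_along(groups), groups, FUN = seq_along)
  colnames(mat) <- paste(groups, compartment, reps, sep = "_")
  if (is.null(rownames(mat))) {
    rownames(mat) <- paste0("g", seq_len(nrow(mat)))
  }
  det <- matrix(detection, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  meta <- data.frame(sample_id = colnames(mat), group = groups,
                     compartment = compartment, replicate = reps,
                     stringsAsFactors = FALSE)
  expression_study(mat, det, meta)
}

# A paired TL+TR study with hand-chosen intensities for partition tests.
make_paired_study <- function(n_genes = 8, seed = 1, noise = 0.05) {
  set.seed(seed)
  groups <- rep(c("T", "R"), each = 6)
  comp <- rep(rep(c("TL", "TR"), each = 3), 2)
  reps <- rep(1:3, 4)
  ids <- paste(groups, comp, reps, sep = "_")
  mat <- matrix(rnorm(n_genes * 12, 2, noise), n_genes, 12,
                dimnames = list(paste0("g", seq_len(n_genes)), ids))
  det <- matrix(0.001, n_genes, 12, dimnames = dimnames(mat))
  meta <- data.frame(sample_id = ids, group = groups, compartment = comp,
                     replicate = reps, stringsAsFactors = FALSE)
  expression_study(mat, det, meta)
}

# Construct a diff_result by hand from per-gene fields (for switchfilter
# tests that need full control over significance patterns).
make_diff_result <- function(genes, z, p = 0.01, fdr = 0.1,
                             significant = NULL, det_fail = FALSE,
                             compartment = "TL") {
  params <- diff_params(n_permutations = 10)
  tab <- data.frame(gene_id = genes,
                    mean_z_test = z / 2, mean_z_ref = -z / 2,
                    z_ratio = z, p_value = rep_len(p, length(genes)),
                    fdr = rep_len(fdr, length(genes)),
                    excluded_by_detection = rep_len(det_fail,
                                                    length(genes)),
                    excluded_by_variance = FALSE, zero_variance = FALSE,
                    significant = FALSE, direction = "none",
                    stringsAsFactors = FALSE)
  rownames(tab) <- genes
  tab <- call_significant(tab, params)
  if (!is.null(significant)) {
    tab$significant <- significant
    tab$direction <- ifelse(!significant, "none",
                            ifelse(tab$z_ratio > 0, "up", "down"))
  }
  structure(list(table = tab,
                 contrast = sample_contrast("T", "R", compartment),
                 params = params,
                 metadata = list(n_retained = sum(!tab$excluded_by_detection))),
            class = "diff_result")
}
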