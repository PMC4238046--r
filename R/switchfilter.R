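# Translatome-exclusive gene calling: combine the TL (polysome-bound) and
# TR (total RNA) contrasts of one condition pair into a four-way partition.

#' Partition genes by translatome/transcriptome significance
#'
#' Implements the exclusivity screen: genes significantly altered in the
#' translatome are eliminated from the exclusive set if a concurrent
#' significant change is observed in the transcriptome. The result is a
#' disjoint cover of the common gene universe:
#' `exclusive_tl` (significant in TL only), `exclusive_tr` (TR only),
#' `shared` (both), `null` (neither). Genes that failed the detection filter
#' in either compartment are assigned to `null` and flagged, not dropped.
#'
#' @param tl,tr [diff_contrast()] results for the translatome and
#'   transcriptome contrasts of the same condition pair. Unequal gene
#'   universes are intersected with a warning; disjoint universes are an
#'   error.
#' @param direction_match If `TRUE`, a transcriptome change only counts as
#'   "concurrent" when its direction agrees with the translatome change;
#'   genes significant in both compartments with opposite directions are
#'   then assigned to `exclusive_tl` (the screen is translatome-centric).
#'   Default `FALSE`: any significant transcriptome change eliminates.
#' @return An object of class `switch_partition` with elements `sets`
#'   (named list of gene-id vectors), `counts`, `table` (gene, label,
#'   detection_failed), and the two input contrasts.
#' @seealso [venn_counts()], [top_table()], [switch_confusion()]
#' @export
partition_switch <- function(tl, tr, direction_match = FALSE) {
  stopifnot(inherits(tl, "diff_result"), inherits(tr, "diff_result"))
  g_tl <- tl$table$gene_id
  g_tr <- tr$table$gene_id
  universe <- intersect(g_tl, g_tr)
  if (length(universe) == 0L) {
    stop("TL and TR gene universes are disjoint", call. = FALSE)
  }
  if (length(universe) < length(g_tl) || length(universe) < length(g_tr)) {
    warning(sprintf(
      "gene universes differ (%d TL, %d TR); using the %d shared genes",
      length(g_tl), length(g_tr), length(universe)), call. = FALSE)
  }
  ttl <- tl$table[match(universe, g_tl), ]
  ttr <- tr$table[match(universe, g_tr), ]
  det_fail <- ttl$excluded_by_detection | ttr$excluded_by_detection
  sig_tl <- ttl$significant & !det_fail
  sig_tr <- ttr$significant & !det_fail
  if (direction_match) {
    concurrent <- sig_tr & ttr$direction == ttl$direction
    label <- ifelse(sig_tl & concurrent, "shared",
             ifelse(sig_tl, "exclusive_tl",
             ifelse(sig_tr, "exclusive_tr", "null")))
  } else {
    label <- ifelse(sig_tl & sig_tr, "shared",
             ifelse(sig_tl, "exclusive_tl",
             ifelse(sig_tr, "exclusive_tr", "null")))
  }
  tab <- data.frame(gene_id = universe, label = label,
                    detection_failed = det_fail,
                    stringsAsFactors = FALSE)
  sets <- split(tab$gene_id, factor(tab$label,
                                    levels = c("exclusive_tl",
                                               "exclusive_tr", "shared",
                                               "null")))
  counts <- vapply(sets, length, integer(1))
  # disjoint-cover invariant, asserted on every run
  stopifnot(sum(counts) == length(universe),
            !anyDuplicated(unlist(sets, use.names = FALSE)))
  structure(list(sets = sets, counts = counts, table = tab,
                 tl_contrast = tl$contrast, tr_contrast = tr$contrast,
                 direction_match = direction_match),
            class = "switch_partition")
}

#' @export
print.switch_partition <- function(x, ...) {
  cat("Switch partition of", sum(x$counts), "genes\n")
  print(x$counts)
  invisible(x)
}

#' Venn counts for a switch partition
#'
#' Summarizes the partition as the counts of the two-set Venn diagram:
#' genes significant only in the translatome, only in the transcriptome,
#' in both, and in neither.
#'
#' @param partition A [partition_switch()] result.
#' @return A list with `counts` (the four set sizes), `universe_size`, and
#'   the two-set Venn view `venn` (tl_only, tr_only, overlap, outside).
#' @export
venn_counts <- function(partition) {
  stopifnot(inherits(partition, "switch_partition"))
  cnt <- partition$counts
  list(counts = as.list(cnt),
       universe_size = sum(cnt),
       venn = list(tl_only = unname(cnt["exclusive_tl"]),
                   tr_only = unname(cnt["exclusive_tr"]),
                   overlap = unname(cnt["shared"]),
                   outside = unname(cnt["null"])))
}

#' Top-ranked exclusive genes
#'
#' Ranks an exclusive set by |Z-ratio| in its own compartment (descending),
#' breaking ties by p-value (ascending) then gene id.
#'
#' @param partition A [partition_switch()] result.
#' @param tl,tr The [diff_contrast()] results used to build the partition.
#' @param n Number of rows to return (default 50); truncated with a message
#'   when the set is smaller.
#' @param set `"exclusive_tl"` (default) or `"exclusive_tr"`.
#' @return Data frame of the ranked genes with their statistics.
#' @export
top_table <- function(partition, tl, tr, n = 50L,
                      set = c("exclusive_tl", "exclusive_tr")) {
  stopifnot(inherits(partition, "switch_partition"))
  set <- match.arg(set)
  n <- assert_count(n, "n")
  src <- if (set == "exclusive_tl") tl else tr
  genes <- partition$sets[[set]]
  tab <- src$table[src$table$gene_id %in% genes, , drop = FALSE]
  ord <- order(-abs(tab$z_ratio), tab$p_value, tab$gene_id)
  tab <- tab[ord, , drop = FALSE]
  if (n > nrow(tab)) {
    message(sprintf("requested %d rows but %s has only %d genes", n, set,
                    nrow(tab)))
    n <- nrow(tab)
  }
  out <- tab[seq_len(n), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Confusion matrix between planted truth and partition labels
#'
#' Cross-tabulates the ground-truth regulation classes of a synthetic study
#' (see [gen_expression()]) against the labels assigned by
#' [partition_switch()], for parameter-recovery checks.
#'
#' @param partition A [partition_switch()] result.
#' @param truth The `truth` data frame from [gen_expression()] (columns
#'   `gene_id`, `class`).
#' @return A contingency table (truth class x partition label).
#' @export
switch_confusion <- function(partition, truth) {
  stopifnot(inherits(partition, "switch_partition"),
            all(c("gene_id", "class") %in% names(truth)))
  common <- intersect(partition$table$gene_id, truth$gene_id)
  lab <- partition$table$label[match(common, partition$table$gene_id)]
  cls <- truth$class[match(common, truth$gene_id)]
  table(truth = factor(cls, levels = c("tl_only", "tr_only", "both",
                                       "null")),
        partition = factor(lab, levels = c("exclusive_tl", "exclusive_tr",
                                           "shared", "null")))
}
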