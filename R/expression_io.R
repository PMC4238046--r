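# Tabular I/O for expression studies. The interchange format is three TSV
# files: an intensity matrix (first column = gene id), a detection p-value
# matrix of identical layout, and a sample sheet. '#' lines are comments.

#' Read an expression study from TSV files
#'
#' @param matrix_path Path to the intensity matrix TSV (first column
#'   `gene_id`, one column per sample).
#' @param detection_path Path to the detection p-value matrix TSV of
#'   identical layout.
#' @param sample_sheet_path Path to the sample sheet TSV with columns
#'   `sample_id`, `group`, `compartment`, `replicate` and optionally
#'   `scale` (`"log10"`, the default, or `"linear"`; linear intensities are
#'   log10-transformed on load and values <= 0 are rejected).
#' @param na_sentinel Optional string; cells equal to it in the intensity
#'   matrix are treated as missing and rejected with a named error. By
#'   default any missing value is an error.
#'
#' @return An [expression_study()] with row and column order exactly as in
#'   the files.
#' @seealso [write_study()]
#' @export
read_study <- function(matrix_path, detection_path, sample_sheet_path,
                       na_sentinel = NULL) {
  for (p in c(matrix_path, detection_path, sample_sheet_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  na_strings <- if (is.null(na_sentinel)) character(0) else na_sentinel
  mat_df <- utils::read.delim(matrix_path, sep = "\t", comment.char = "#",
                              header = TRUE, check.names = FALSE,
                              stringsAsFactors = FALSE,
                              na.strings = na_strings)
  det_df <- utils::read.delim(detection_path, sep = "\t", comment.char = "#",
                              header = TRUE, check.names = FALSE,
                              stringsAsFactors = FALSE,
                              na.strings = na_strings)
  sheet <- read_tsv(sample_sheet_path)

  to_matrix <- function(df, what) {
    if (ncol(df) < 2L) stop(what, ": expected gene id column plus samples",
                            call. = FALSE)
    ids <- as.character(df[[1L]])
    if (anyDuplicated(ids)) {
      stop(what, ": duplicate gene id '", ids[duplicated(ids)][1], "'",
           call. = FALSE)
    }
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m)) stop(what, ": non-numeric entries", call. = FALSE)
    rownames(m) <- ids
    m
  }
  mat <- to_matrix(mat_df, "intensity matrix")
  det <- to_matrix(det_df, "detection matrix")
  if (!identical(dim(mat), dim(det)) ||
      !identical(rownames(mat), rownames(det)) ||
      !identical(colnames(mat), colnames(det))) {
    stop("intensity and detection matrices disagree in shape or labels",
         call. = FALSE)
  }
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing intensity at gene '%s', sample '%s'",
                 rownames(mat)[bad[1L]], colnames(mat)[bad[2L]]),
         call. = FALSE)
  }
  if (!identical(as.character(sheet$sample_id), colnames(mat))) {
    stop("sample sheet order disagrees with matrix columns", call. = FALSE)
  }
  scale <- unique(sheet$scale %||% "log10")
  if (length(scale) != 1L || !scale %in% c("log10", "linear")) {
    stop("sample sheet 'scale' must be uniformly 'log10' or 'linear'",
         call. = FALSE)
  }
  if (scale == "linear") {
    if (any(mat <= 0)) {
      bad <- which(mat <= 0, arr.ind = TRUE)[1L, ]
      stop(sprintf(
        "linear intensities must be positive; gene '%s', sample '%s'",
        rownames(mat)[bad[1L]], colnames(mat)[bad[2L]]), call. = FALSE)
    }
    mat <- log10(mat)
  }
  sheet$scale <- NULL
  expression_study(mat, det, sheet)
}

#' Write an expression study to TSV files
#'
#' Inverse of [read_study()]: writes `matrix.tsv`, `detection.tsv` and
#' `samples.tsv` (log10 scale) into `dir`.
#'
#' @param study An [expression_study()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the three file paths.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "expression_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("matrix.tsv", "detection.tsv", "samples.tsv"))
  mat_df <- data.frame(gene_id = rownames(study$log_intensity),
                       study$log_intensity, check.names = FALSE)
  det_df <- data.frame(gene_id = rownames(study$detection_p),
                       study$detection_p, check.names = FALSE)
  sheet <- study$sample_meta
  sheet$scale <- "log10"
  write_tsv(mat_df, paths[1L])
  write_tsv(det_df, paths[2L])
  write_tsv(sheet, paths[3L])
  invisible(paths)
}
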