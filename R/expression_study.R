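#' Expression study container
#'
#' Holds a paired translatome/transcriptome microarray-style study: a gene by
#' sample matrix of log10 intensities, a matching matrix of per-observation
#' detection p-values, and per-sample annotations (condition group,
#' compartment, replicate index). All downstream differential analysis
#' consumes this container.
#'
#' @param log_intensity Numeric gene x sample matrix of log10 intensities,
#'   with unique rownames (gene identifiers) and colnames (sample
#'   identifiers).
#' @param detection_p Numeric matrix of the same shape with detection
#'   p-values in `[0, 1]`.
#' @param sample_meta Data frame with one row per sample and columns
#'   `sample_id`, `group`, `compartment` (one of `"TL"` for translatome,
#'   `"TR"` for transcriptome) and `replicate`. Row order must match the
#'   column order of the matrices.
#'
#' @return An object of class `expression_study`.
#'
#' @details Validation enforces: matching dimensions and dimnames, unique
#'   gene and sample identifiers, detection p-values in `[0, 1]`, the
#'   `TL`/`TR` compartment vocabulary, finite intensities, and at least two
#'   replicates for every (group, compartment) cell.
#'
#' @seealso [read_study()], [write_study()], [diff_contrast()]
#' @export
#' @examples
#' m <- matrix(rnorm(12, 2, 0.3), 3, 4,
#'             dimnames = list(paste0("g", 1:3),
#'                             c("A_TL_1", "A_TL_2", "B_TL_1", "B_TL_2")))
#' meta <- data.frame(sample_id = colnames(m),
#'                    group = rep(c("A", "B"), each = 2),
#'                    compartment = "TL", replicate = c(1, 2, 1, 2))
#' study <- expression_study(m, matrix(0.001, 3, 4, dimnames = dimnames(m)), meta)
#' study
expression_study <- function(log_intensity, detection_p, sample_meta) {
  if (!is.matrix(log_intensity) || !is.numeric(log_intensity)) {
    stop("'log_intensity' must be a numeric matrix", call. = FALSE)
  }
  if (!is.matrix(detection_p) || !is.numeric(detection_p)) {
    stop("'detection_p' must be a numeric matrix", call. = FALSE)
  }
  if (!identical(dim(log_intensity), dim(detection_p))) {
    stop("'log_intensity' and 'detection_p' must have identical dimensions",
         call. = FALSE)
  }
  genes <- rownames(log_intensity)
  samples <- colnames(log_intensity)
  if (is.null(genes) || anyDuplicated(genes)) {
    dup <- if (is.null(genes)) "<missing rownames>" else
      genes[duplicated(genes)][1]
    stop("gene identifiers must be present and unique; offending id: ", dup,
         call. = FALSE)
  }
  if (is.null(samples) || anyDuplicated(samples)) {
    stop("sample identifiers must be present and unique", call. = FALSE)
  }
  if (!is.null(rownames(detection_p)) &&
      !identical(rownames(detection_p), genes)) {
    stop("detection_p rownames disagree with log_intensity", call. = FALSE)
  }
  if (anyNA(log_intensity) || any(!is.finite(log_intensity))) {
    stop("log_intensity contains missing or non-finite values", call. = FALSE)
  }
  if (anyNA(detection_p) || any(detection_p < 0 | detection_p > 1)) {
    stop("detection_p values must lie in [0, 1]", call. = FALSE)
  }
  sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
  req <- c("sample_id", "group", "compartment", "replicate")
  missing_cols <- setdiff(req, names(sample_meta))
  if (length(missing_cols)) {
    stop("sample_meta lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!identical(as.character(sample_meta$sample_id), samples)) {
    stop("sample_meta$sample_id must match matrix column order", call. = FALSE)
  }
  bad_comp <- setdiff(unique(sample_meta$compartment), c("TL", "TR"))
  if (length(bad_comp)) {
    stop("unknown compartment label(s): ", paste(bad_comp, collapse = ", "),
         "; expected 'TL' or 'TR'", call. = FALSE)
  }
  cell <- table(sample_meta$group, sample_meta$compartment)
  if (any(cell > 0 & cell < 2)) {
    stop("every (group, compartment) present must have >= 2 replicates",
         call. = FALSE)
  }
  dimnames(detection_p) <- dimnames(log_intensity)
  structure(list(log_intensity = log_intensity,
                 detection_p = detection_p,
                 sample_meta = sample_meta),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat("Expression study:", nrow(x$log_intensity), "genes x",
      ncol(x$log_intensity), "samples\n")
  tab <- table(x$sample_meta$group, x$sample_meta$compartment)
  cat("Samples per (group, compartment):\n")
  print(tab)
  invisible(x)
}

#' @export
dim.expression_study <- function(x) dim(x$log_intensity)

#' Define a two-group contrast within one compartment
#'
#' @param test,reference Condition group labels to compare (test vs
#'   reference).
#' @param compartment `"TL"` (translatome) or `"TR"` (transcriptome).
#' @return An object of class `sample_contrast`.
#' @export
#' @examples
#' sample_contrast("E1", "EV", "TL")
sample_contrast <- function(test, reference, compartment = c("TL", "TR")) {
  compartment <- match.arg(compartment)
  stopifnot(is.character(test), length(test) == 1L,
            is.character(reference), length(reference) == 1L)
  if (test == reference) {
    stop("test and reference groups must differ", call. = FALSE)
  }
  structure(list(test = test, reference = reference,
                 compartment = compartment),
            class = "sample_contrast")
}

#' @export
print.sample_contrast <- function(x, ...) {
  cat(sprintf("Contrast: %s vs %s [%s]\n", x$test, x$reference,
              x$compartment))
  invisible(x)
}

#' @method format sample_contrast
#' @export
format.sample_contrast <- function(x, ...) {
  sprintf("%s_vs_%s_%s", x$test, x$reference, x$compartment)
}

# Resolve a contrast into the column indices of its test and reference
# samples; errors if either (group, compartment) cell is absent or has
# fewer than two replicates.
contrast_columns <- function(study, contrast) {
  meta <- study$sample_meta
  test_idx <- which(meta$group == contrast$test &
                      meta$compartment == contrast$compartment)
  ref_idx <- which(meta$group == contrast$reference &
                     meta$compartment == contrast$compartment)
  if (length(test_idx) < 2L || length(ref_idx) < 2L) {
    stop(sprintf(
      "contrast %s vs %s [%s] needs >= 2 replicates per group (found %d and %d)",
      contrast$test, contrast$reference, contrast$compartment,
      length(test_idx), length(ref_idx)), call. = FALSE)
  }
  list(test = test_idx, ref = ref_idx)
}
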