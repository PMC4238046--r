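# Window-constrained motif over-representation in 5'-UTRs. Coordinates are
# 0-based; position 0 of every sequence is the TSS; the search window is
# half-open [from, to), and a match counts when its *start* lies inside the
# window even if it extends past the window end. Gene-level counting: a
# gene counts once however many matches it carries.

iupac_ok <- function(x) !grepl("[^ACGTRYSWKMBDHVN]", toupper(x))

check_motif <- function(motif) {
  if (!is.character(motif) || length(motif) != 1L || nchar(motif) == 0L) {
    stop("'motif' must be a non-empty string", call. = FALSE)
  }
  motif <- toupper(motif)
  if (!iupac_ok(motif)) {
    stop("'motif' contains non-IUPAC characters", call. = FALSE)
  }
  motif
}

as_dna_set <- function(utrs) {
  if (inherits(utrs, "DNAStringSet")) return(utrs)
  if (is.character(utrs)) {
    if (is.null(names(utrs))) stop("UTR sequences must be named",
                                   call. = FALSE)
    if (!all(iupac_ok(utrs))) {
      stop("UTR sequences contain non-IUPAC characters", call. = FALSE)
    }
    return(Biostrings::DNAStringSet(toupper(utrs)))
  }
  stop("'utrs' must be a named character vector or DNAStringSet",
       call. = FALSE)
}

# Extract the windowed part of each sequence, extended by k-1 nt past the
# window end so that every match whose start is inside the window is fully
# contained; no match can then *start* beyond the window.
window_seqs <- function(utrs, window, k) {
  w <- Biostrings::width(utrs)
  from <- pmin(window[1] + 1L, w + 1L)
  to <- pmin(window[2] + k - 1L, w)
  keep <- from <= to
  out <- utrs
  out[keep] <- Biostrings::subseq(utrs[keep], start = from[keep],
                                  end = to[keep])
  if (any(!keep)) out[!keep] <- Biostrings::DNAStringSet("")[rep(1, sum(!keep))]
  out
}

#' Scan one sequence for motif matches inside a TSS-anchored window
#'
#' @param seq A DNA sequence (character or `DNAString`); position 0 is the
#'   TSS.
#' @param motif Motif string; IUPAC degeneracy codes are allowed.
#' @param window Half-open 0-based interval `c(from, to)` of allowed match
#'   starts (default `c(0, 200)`).
#' @return Sorted integer vector of 0-based match start offsets; overlapping
#'   matches are all reported.
#' @export
#' @examples
#' scan_window("ATATAT", "ATAT", c(0, 200))  # starts 0 and 2
scan_window <- function(seq, motif, window = c(0, 200)) {
  motif <- check_motif(motif)
  seq <- toupper(as.character(seq))
  if (!iupac_ok(seq)) {
    stop("sequence contains non-IUPAC characters", call. = FALSE)
  }
  m <- Biostrings::matchPattern(motif, Biostrings::DNAString(seq),
                                fixed = FALSE)
  s0 <- BiocGenerics::start(m) - 1L
  sort(s0[s0 >= window[1] & s0 < window[2]])
}

check_gene_sets <- function(targets, universe) {
  if (anyDuplicated(targets)) {
    stop("duplicate entries in target gene list", call. = FALSE)
  }
  if (anyDuplicated(universe)) {
    stop("duplicate entries in universe gene list", call. = FALSE)
  }
  if (!all(targets %in% universe)) {
    stop("targets must be a subset of the universe", call. = FALSE)
  }
}

drop_missing_utrs <- function(genes, utrs, what) {
  missing <- setdiff(genes, names(utrs))
  if (length(missing)) {
    warning(sprintf("%d %s gene(s) lack a UTR and were excluded (e.g. %s)",
                    length(missing), what, missing[1]), call. = FALSE)
    genes <- setdiff(genes, missing)
  }
  genes
}

#' Hypergeometric motif over-representation
#'
#' Counts, at the gene level, how many universe genes (`K` of `N`) and how
#' many target genes (`k` of `n`) carry at least one motif match starting
#' inside the window, and scores the target excess with the hypergeometric
#' upper-tail probability `P[X >= k]`. The enrichment factor is
#' `(k/n) / (K/N)`.
#'
#' @param targets,universe Gene-id vectors, `targets` a subset of
#'   `universe`. Genes lacking a UTR are excluded with a warning and the
#'   counts adjusted.
#' @param utrs Named `DNAStringSet` (or named character vector) of 5'-UTR
#'   sequences, TSS at position 0.
#' @param motif Motif string (IUPAC codes allowed).
#' @param window Half-open 0-based start window (default `c(0, 200)`).
#' @return An object of class `motif_enrichment` with fields `motif`, `N`,
#'   `K`, `n`, `k`, `p_hg`, `enrichment`, `p_adj` (equal to `p_hg` here;
#'   Bonferroni applies in [discover_motifs()]), and `positions` (0-based
#'   match starts over target genes).
#' @export
enrich_motif <- function(targets, universe, utrs, motif,
                         window = c(0, 200)) {
  motif <- check_motif(motif)
  check_gene_sets(targets, universe)
  utrs <- as_dna_set(utrs)
  universe <- drop_missing_utrs(universe, utrs, "universe")
  targets <- intersect(drop_missing_utrs(targets, utrs, "target"), universe)
  k_len <- nchar(motif)
  ws <- window_seqs(utrs[universe], window, k_len)
  cnt <- Biostrings::vcountPattern(motif, ws, fixed = FALSE)
  names(cnt) <- universe
  N <- length(universe)
  K <- sum(cnt > 0)
  n <- length(targets)
  k <- sum(cnt[targets] > 0)
  p_hg <- if (K == 0) 1 else
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  enrichment <- if (K == 0 || n == 0) 0 else (k / n) / (K / N)
  tg_ws <- ws[targets]
  starts <- Biostrings::startIndex(
    Biostrings::vmatchPattern(motif, tg_ws, fixed = FALSE))
  positions <- unlist(lapply(starts, function(s) {
    if (is.null(s)) integer(0) else s - 1L + window[1]
  }), use.names = FALSE)
  structure(list(motif = motif, N = N, K = K, n = n, k = k,
                 p_hg = p_hg, enrichment = enrichment, p_adj = p_hg,
                 positions = positions, window = window),
            class = "motif_enrichment")
}

#' @export
print.motif_enrichment <- function(x, ...) {
  cat(sprintf("Motif %s: %d/%d targets vs %d/%d universe (window [%d,%d))\n",
              x$motif, x$k, x$n, x$K, x$N, x$window[1], x$window[2]))
  cat(sprintf("  enrichment %.3g, hypergeometric p = %.3g, adjusted p = %.3g\n",
              x$enrichment, x$p_hg, x$p_adj))
  invisible(x)
}

#' Exhaustive k-mer over-representation scan
#'
#' Enumerates every exact ACGT k-mer observed, at the gene level, in at
#' least `min_support` target windows, scores each with the hypergeometric
#' over-representation test of [enrich_motif()], applies a Bonferroni
#' correction over the number of scored k-mers, and ranks by hypergeometric
#' p (ties broken by descending enrichment, then k-mer).
#'
#' @inheritParams enrich_motif
#' @param k_len Motif length (default 10).
#' @param min_support Minimum number of distinct target genes a candidate
#'   must occur in (default 2).
#' @param top_m Keep at most this many ranked motifs (default all).
#' @return A data frame of class `motif_discovery` with one row per scored
#'   k-mer (`motif`, `k`, `K`, `n`, `N`, `enrichment`, `p_hg`, `p_adj`);
#'   empty, with a message, when no candidates exist.
#' @export
discover_motifs <- function(targets, universe, utrs, k_len = 10L,
                            window = c(0, 200), min_support = 2L,
                            top_m = Inf) {
  k_len <- assert_count(k_len, "k_len")
  check_gene_sets(targets, universe)
  utrs <- as_dna_set(utrs)
  universe <- drop_missing_utrs(universe, utrs, "universe")
  targets <- intersect(drop_missing_utrs(targets, utrs, "target"), universe)
  ws_all <- window_seqs(utrs[universe], window, k_len)
  tg_chr <- as.character(ws_all[targets])
  kmer_sets <- lapply(tg_chr, function(s) {
    L <- nchar(s)
    if (L < k_len) return(character(0))
    unique(substring(s, seq_len(L - k_len + 1L),
                     seq_len(L - k_len + 1L) + k_len - 1L))
  })
  support <- table(unlist(kmer_sets, use.names = FALSE))
  candidates <- names(support)[support >= min_support]
  candidates <- candidates[!grepl("[^ACGT]", candidates)]
  empty <- data.frame(motif = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0),
                      enrichment = numeric(0), p_hg = numeric(0),
                      p_adj = numeric(0), stringsAsFactors = FALSE)
  class(empty) <- c("motif_discovery", "data.frame")
  if (length(candidates) == 0L) {
    message("no candidate k-mers occur in >= ", min_support,
            " target windows")
    return(empty)
  }
  pd <- Biostrings::PDict(candidates)
  cnt <- Biostrings::vcountPDict(pd, ws_all)  # motifs x universe genes
  hit <- cnt > 0
  tg_idx <- match(targets, universe)
  N <- length(universe)
  n <- length(targets)
  K <- as.integer(rowSums(hit))
  k <- as.integer(rowSums(hit[, tg_idx, drop = FALSE]))
  p_hg <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  m <- length(candidates)
  out <- data.frame(motif = candidates, k = k, K = K, n = n, N = N,
                    enrichment = (k / n) / (K / N),
                    p_hg = p_hg,
                    p_adj = pmin(1, p_hg * m),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_hg, -out$enrichment, out$motif), , drop = FALSE]
  if (is.finite(top_m)) out <- out[seq_len(min(nrow(out), top_m)), ,
                                   drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_scored") <- m
  class(out) <- c("motif_discovery", "data.frame")
  out
}

#' Bias diagnostics for a motif enrichment
#'
#' Screens the comparison for the confounders that inflate naive motif
#' enrichment: GC-content and UTR-length differences between target and
#' background sequences (two-sample Wilcoxon rank-sum tests), strand bias
#' (motif match counts on the given strand vs the reverse complement,
#' exact binomial test against 0.5), and positional clustering of match
#' starts within the window (Kolmogorov-Smirnov test against uniform).
#'
#' @inheritParams enrich_motif
#' @return An object of class `bias_report` with components `gc_test`,
#'   `length_test`, `strand_bias` and `localization` (statistic + p each;
#'   localization is `NA` with a reason when there are fewer than 5
#'   matches).
#' @export
bias_diagnostics <- function(targets, universe, utrs, motif,
                             window = c(0, 200)) {
  motif <- check_motif(motif)
  check_gene_sets(targets, universe)
  utrs <- as_dna_set(utrs)
  universe <- drop_missing_utrs(universe, utrs, "universe")
  targets <- intersect(drop_missing_utrs(targets, utrs, "target"), universe)
  background <- setdiff(universe, targets)
  gc_frac <- Biostrings::letterFrequency(utrs[universe], "GC",
                                         as.prob = TRUE)[, 1L]
  names(gc_frac) <- universe
  lens <- stats::setNames(Biostrings::width(utrs[universe]), universe)

  two_sample <- function(vals) {
    a <- vals[targets]; b <- vals[background]
    if (length(b) == 0L || length(unique(c(a, b))) == 1L) {
      return(list(statistic = NA_real_, p = 1))
    }
    wt <- suppressWarnings(stats::wilcox.test(a, b))
    list(statistic = unname(wt$statistic), p = wt$p.value)
  }
  gc_test <- two_sample(gc_frac)
  length_test <- two_sample(lens)

  k_len <- nchar(motif)
  tg_ws <- window_seqs(utrs[targets], window, k_len)
  sense <- sum(Biostrings::vcountPattern(motif, tg_ws, fixed = FALSE))
  anti <- sum(Biostrings::vcountPattern(
    motif, Biostrings::reverseComplement(tg_ws), fixed = FALSE))
  strand_p <- if (sense + anti == 0) 1 else
    stats::binom.test(sense, sense + anti, 0.5)$p.value
  strand_bias <- list(sense = sense, antisense = anti, p = strand_p)

  starts <- Biostrings::startIndex(
    Biostrings::vmatchPattern(motif, tg_ws, fixed = FALSE))
  positions <- unlist(lapply(starts, function(s) {
    if (is.null(s)) integer(0) else s - 1L + window[1]
  }), use.names = FALSE)
  localization <- if (length(positions) < 5L) {
    list(statistic = NA_real_, p = NA_real_,
         reason = sprintf("only %d matches (need >= 5)",
                          length(positions)))
  } else {
    ks <- suppressWarnings(stats::ks.test(positions, "punif",
                                          window[1], window[2]))
    list(statistic = unname(ks$statistic), p = ks$p.value, reason = NULL)
  }
  structure(list(gc_test = gc_test, length_test = length_test,
                 strand_bias = strand_bias, localization = localization,
                 motif = motif, window = window,
                 n_matches = length(positions)),
            class = "bias_report")
}

#' @export
print.bias_report <- function(x, ...) {
  cat("Bias diagnostics for motif", x$motif, "\n")
  cat(sprintf("  GC bias:        p = %.3g\n", x$gc_test$p))
  cat(sprintf("  Length bias:    p = %.3g\n", x$length_test$p))
  cat(sprintf("  Strand bias:    %d sense / %d antisense, p = %.3g\n",
              x$strand_bias$sense, x$strand_bias$antisense,
              x$strand_bias$p))
  if (is.na(x$localization$p)) {
    cat("  Localization:   NA (", x$localization$reason, ")\n", sep = "")
  } else {
    cat(sprintf("  Localization:   D = %.3f, p = %.3g\n",
                x$localization$statistic, x$localization$p))
  }
  invisible(x)
}

#' Compare two position weight matrices
#'
#' Slides the candidate PWM along the reference without gaps and reports
#' the offset maximizing the mean per-column Pearson correlation, requiring
#' at least `min_overlap` overlapping columns. Columns with zero variance
#' (e.g. uniform) contribute 0 to the mean. Used to compare discovered
#' motifs against the 5' terminal oligopyrimidine (TOP) reference.
#'
#' @param candidate,reference Column-stochastic 4 x width matrices over
#'   ACGT (rows in ACGT order, or rownames to that effect); columns must
#'   sum to 1 within 1e-6.
#' @param min_overlap Minimum overlapping columns (default 4).
#' @return A list with `score` in `[-1, 1]` and `offset` (columns the
#'   candidate start is shifted right of the reference start).
#' @export
compare_pwm <- function(candidate, reference, min_overlap = 4L) {
  fix <- function(m, what) {
    m <- as.matrix(m)
    if (nrow(m) != 4L) stop(what, " must have 4 rows (ACGT)", call. = FALSE)
    if (!is.null(rownames(m))) {
      if (!setequal(rownames(m), c("A", "C", "G", "T"))) {
        stop(what, " rownames must be A, C, G, T", call. = FALSE)
      }
      m <- m[c("A", "C", "G", "T"), , drop = FALSE]
    }
    if (any(abs(colSums(m) - 1) > 1e-6)) {
      stop(what, " columns must sum to 1", call. = FALSE)
    }
    m
  }
  candidate <- fix(candidate, "candidate")
  reference <- fix(reference, "reference")
  wc <- ncol(candidate); wr <- ncol(reference)
  min_overlap <- min(min_overlap, wc, wr)
  best <- list(score = -Inf, offset = NA_integer_)
  for (off in seq(-(wc - min_overlap), wr - min_overlap)) {
    c_cols <- seq(max(1L, 1L - off), min(wc, wr - off))
    r_cols <- c_cols + off
    if (length(c_cols) < min_overlap) next
    contribs <- vapply(seq_along(c_cols), function(j) {
      a <- candidate[, c_cols[j]]; b <- reference[, r_cols[j]]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
      stats::cor(a, b)
    }, numeric(1))
    score <- mean(contribs)
    if (score > best$score + 1e-12 ||
        (abs(score - best$score) <= 1e-12 &&
         abs(off) < abs(best$offset))) {
      best <- list(score = score, offset = off)
    }
  }
  best
}

#' Build a position weight matrix from aligned sequences
#'
#' Column-wise base frequencies of equal-length ACGT sequences, with an
#' optional pseudocount.
#'
#' @param seqs Character vector of equal-length ACGT strings.
#' @param pseudocount Added to each cell before normalization (default 0).
#' @return A column-stochastic 4 x width matrix with rownames ACGT.
#' @export
pwm_from_sequences <- function(seqs, pseudocount = 0) {
  stopifnot(is.character(seqs), length(seqs) >= 1L)
  w <- unique(nchar(seqs))
  if (length(w) != 1L) stop("sequences must have equal length",
                            call. = FALSE)
  if (any(grepl("[^ACGT]", toupper(seqs)))) {
    stop("sequences must be over ACGT", call. = FALSE)
  }
  mat <- matrix(pseudocount, 4L, w, dimnames = list(c("A", "C", "G", "T"),
                                                    NULL))
  for (s in toupper(seqs)) {
    bases <- strsplit(s, "")[[1L]]
    for (j in seq_len(w)) mat[bases[j], j] <- mat[bases[j], j] + 1
  }
  sweep(mat, 2L, colSums(mat), "/")
}

#' Read / write a PWM as 4-row TSV
#'
#' @param path File path; rows A, C, G, T, one column per motif position.
#' @return `read_pwm()` returns the matrix; `write_pwm()` its path,
#'   invisibly.
#' @export
read_pwm <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  colnames(m) <- NULL
  m[c("A", "C", "G", "T"), , drop = FALSE]
}

#' @rdname read_pwm
#' @param pwm The matrix to write.
#' @export
write_pwm <- function(pwm, path) {
  df <- data.frame(base = rownames(pwm), pwm, check.names = FALSE)
  write_tsv(df, path)
  invisible(path)
}
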