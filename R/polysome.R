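# Spike-in-normalized quantification of transcript distribution across
# sucrose-gradient fractions. A fixed quantity of exogenous luciferase mRNA
# is spiked into each fraction's RNA, so the efficiency^(Ct_spike - Ct_target)
# ratio cancels per-fraction recovery differences; percentages are of the
# summed normalized quantities.

#' Spike-in normalization of a per-fraction Ct table
#'
#' For each fraction, the relative target quantity is
#' `efficiency^(Ct_spike - Ct_target)` (perfect doubling per cycle at the
#' default efficiency 2), and the percent column rescales quantities to sum
#' to 100. Adding any constant to both Cts of one fraction (an RNA-recovery
#' difference) leaves its percent unchanged.
#'
#' @param ct_table Data frame with columns `fraction`, `target_ct`,
#'   `spike_ct`, one row per fraction (a single replicate).
#' @param efficiency Amplification efficiency per PCR cycle, in `(1, 2]`
#'   (default 2).
#' @param heavy_set Fraction indices counted as heavy polysomes (default
#'   `9:11`).
#' @return An object of class `fraction_profile`: a data frame with
#'   `fraction`, `quantity`, `percent`, and attributes `heavy_set` and
#'   `efficiency`.
#' @export
#' @examples
#' ct <- data.frame(fraction = 1:11, target_ct = 25, spike_ct = 20)
#' normalize_fractions(ct)  # flat profile: each percent = 100/11
normalize_fractions <- function(ct_table, efficiency = 2,
                                heavy_set = 9:11) {
  stopifnot(is.data.frame(ct_table),
            all(c("fraction", "target_ct", "spike_ct") %in%
                  names(ct_table)))
  efficiency <- assert_number(efficiency, "efficiency", min = 1, max = 2,
                              open_min = TRUE)
  fr <- ct_table$fraction
  if (anyDuplicated(fr)) stop("duplicate fraction rows", call. = FALSE)
  expected <- seq_len(max(fr))
  if (!setequal(fr, expected)) {
    stop("missing fraction(s): ",
         paste(setdiff(expected, fr), collapse = ", "), call. = FALSE)
  }
  if (anyNA(ct_table$target_ct) || anyNA(ct_table$spike_ct)) {
    stop("Ct values must not be missing", call. = FALSE)
  }
  if (!all(heavy_set %in% fr)) {
    stop("'heavy_set' outside fraction range", call. = FALSE)
  }
  ord <- order(fr)
  q <- efficiency^(ct_table$spike_ct[ord] - ct_table$target_ct[ord])
  out <- data.frame(fraction = fr[ord], quantity = q,
                    percent = 100 * q / sum(q))
  attr(out, "heavy_set") <- heavy_set
  attr(out, "efficiency") <- efficiency
  class(out) <- c("fraction_profile", "data.frame")
  out
}

#' @export
print.fraction_profile <- function(x, ...) {
  cat("Fraction profile over", nrow(x), "fractions; heavy set {",
      paste(attr(x, "heavy_set"), collapse = ","), "} carries ",
      sprintf("%.1f%%\n", heavy_share(x)), sep = "")
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Heavy-polysome share of a fraction profile
#'
#' @param profile A [normalize_fractions()] result.
#' @param heavy_set Fraction indices to sum over (default the profile's
#'   own attribute).
#' @return Percent of total signal in the heavy fractions.
#' @export
heavy_share <- function(profile, heavy_set = NULL) {
  stopifnot(inherits(profile, "fraction_profile"))
  heavy_set <- heavy_set %||% attr(profile, "heavy_set")
  if (!all(heavy_set %in% profile$fraction)) {
    stop("'heavy_set' outside fraction range", call. = FALSE)
  }
  sum(profile$percent[profile$fraction %in% heavy_set])
}

# Equal-variance two-sample t-test guarded for degenerate inputs: identical
# constant groups give p = 1; zero variance with different means gives
# p = 0.
guarded_t <- function(a, b) {
  if (length(unique(c(a, b))) == 1L) return(list(diff = 0, p = 1))
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    return(list(diff = mean(a) - mean(b), p = 0))
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(diff = mean(a) - mean(b), p = tt$p.value)
}

#' Compare replicate fraction profiles between two conditions
#'
#' Per-fraction percentages are compared replicate-wise with two-tailed
#' equal-variance t-tests, and the heavy-polysome shares likewise.
#' Percentages are computed per replicate and then averaged, matching the
#' per-experiment spike-in normalization.
#'
#' @param a,b Lists of [normalize_fractions()] profiles (one per
#'   replicate), at least two each, with identical fraction grids.
#' @return An object of class `profile_comparison`: `per_fraction` (data
#'   frame of means, difference and p per fraction) and `heavy` (shares,
#'   difference, direction, p).
#' @export
compare_profiles <- function(a, b) {
  check_side <- function(x, what) {
    if (inherits(x, "fraction_profile")) x <- list(x)
    if (!is.list(x) || length(x) < 2L ||
        !all(vapply(x, inherits, logical(1), "fraction_profile"))) {
      stop("'", what, "' must be a list of >= 2 fraction profiles",
           call. = FALSE)
    }
    x
  }
  a <- check_side(a, "a")
  b <- check_side(b, "b")
  nf <- unique(c(vapply(a, nrow, integer(1)), vapply(b, nrow, integer(1))))
  if (length(nf) != 1L) {
    stop("profiles have mismatched fraction counts", call. = FALSE)
  }
  pa <- do.call(rbind, lapply(a, function(p) p$percent))  # reps x fractions
  pb <- do.call(rbind, lapply(b, function(p) p$percent))
  fr <- a[[1L]]$fraction
  per_fraction <- do.call(rbind, lapply(seq_len(nf), function(j) {
    g <- guarded_t(pa[, j], pb[, j])
    data.frame(fraction = fr[j], mean_a = mean(pa[, j]),
               mean_b = mean(pb[, j]), difference = g$diff, p_value = g$p)
  }))
  ha <- vapply(a, heavy_share, numeric(1))
  hb <- vapply(b, heavy_share, numeric(1))
  gh <- guarded_t(ha, hb)
  heavy <- list(share_a = mean(ha), share_b = mean(hb),
                difference = gh$diff,
                direction = if (gh$diff > 0) "a_heavier"
                            else if (gh$diff < 0) "b_heavier" else "equal",
                p_value = gh$p)
  structure(list(per_fraction = per_fraction, heavy = heavy),
            class = "profile_comparison")
}

#' @export
print.profile_comparison <- function(x, ...) {
  cat("Profile comparison over", nrow(x$per_fraction), "fractions\n")
  cat(sprintf("  heavy share: %.1f%% vs %.1f%% (diff %+.1f, %s, p = %.3g)\n",
              x$heavy$share_a, x$heavy$share_b, x$heavy$difference,
              x$heavy$direction, x$heavy$p_value))
  invisible(x)
}

#' Build replicate profiles from a long Ct table
#'
#' @param ct_table Data frame with columns `fraction`, `replicate`,
#'   `target_ct`, `spike_ct` and optionally `condition`.
#' @inheritParams normalize_fractions
#' @return Without a `condition` column, a list of [normalize_fractions()]
#'   profiles (one per replicate); with one, a named list of such lists.
#' @export
profiles_from_table <- function(ct_table, efficiency = 2,
                                heavy_set = 9:11) {
  stopifnot(is.data.frame(ct_table), "replicate" %in% names(ct_table))
  one_cond <- function(df) {
    lapply(split(df, df$replicate), normalize_fractions,
           efficiency = efficiency, heavy_set = heavy_set)
  }
  if ("condition" %in% names(ct_table)) {
    lapply(split(ct_table, ct_table$condition), one_cond)
  } else {
    one_cond(ct_table)
  }
}

#' Read a per-fraction Ct table from TSV
#'
#' @param path TSV with columns `fraction`, `target_ct`, `spike_ct` and
#'   optionally `replicate`, `condition`.
#' @return The data frame.
#' @export
read_ct_table <- function(path) {
  df <- read_tsv(path)
  need <- c("fraction", "target_ct", "spike_ct")
  if (!all(need %in% names(df))) {
    stop("Ct table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df
}
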