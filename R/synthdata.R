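# Seeded generators for every input the pipeline consumes, with planted
# ground truth. Defaults emulate the structure of a paired
# translatome/transcriptome bead-array study: two conditions, three
# biological replicates, both compartments.

#' Configuration for the paired-study generator
#'
#' @param n_genes Number of genes.
#' @param n_reps Biological replicates per (group, compartment) (default 3).
#' @param groups Condition labels; the first is the unperturbed reference,
#'   effects are planted in every other group (default `c("EV", "E1")`,
#'   empty vector vs effector).
#' @param class_fractions Named proportions over the regulation classes
#'   `tl_only` (translation-only change), `tr_only` (transcription-only),
#'   `both`, and `null`; must sum to 1. Default plants 4% of genes in each
#'   regulated class.
#' @param effect_size Target mean |Z-ratio| of regulated genes in their
#'   regulated compartment (dimensionless; default 3). Because the Z-ratio
#'   standardizes by the across-gene spread (and planted effects also
#'   inflate the per-sample SD used in Z-scoring), the achievable mean
#'   |Z-ratio| is bounded for any planted fraction; requests beyond the
#'   bound saturate at the largest achievable value with a warning.
#' @param noise_sd Within-group SD on the log10-intensity scale
#'   (default 0.2).
#' @param detection_fail_rate Probability that an observation draws a
#'   detection p-value above 0.02 (default 0.05).
#' @param baseline_range Range of per-gene baseline log10 intensities
#'   (default `c(1, 3.5)`).
#' @param seed Integer seed.
#' @return A validated list of class `gen_config`.
#' @export
gen_config <- function(n_genes = 2000L, n_reps = 3L,
                       groups = c("EV", "E1"),
                       class_fractions = c(tl_only = 0.04, tr_only = 0.04,
                                           both = 0.04, null = 0.88),
                       effect_size = 3, noise_sd = 0.2,
                       detection_fail_rate = 0.05,
                       baseline_range = c(1, 3.5),
                       seed = 1L) {
  n_genes <- assert_count(n_genes, "n_genes")
  n_reps <- assert_count(n_reps, "n_reps", min = 2L)
  if (!is.character(groups) || length(groups) < 2L ||
      anyDuplicated(groups)) {
    stop("'groups' must be >= 2 distinct labels", call. = FALSE)
  }
  cls <- c("tl_only", "tr_only", "both", "null")
  if (!all(cls %in% names(class_fractions)) ||
      any(class_fractions < 0) ||
      abs(sum(class_fractions) - 1) > 1e-9) {
    stop("'class_fractions' must be named over {tl_only, tr_only, both, null} and sum to 1",
         call. = FALSE)
  }
  structure(list(
    n_genes = n_genes, n_reps = n_reps, groups = groups,
    class_fractions = class_fractions[cls],
    effect_size = assert_number(effect_size, "effect_size", min = 0),
    noise_sd = assert_number(noise_sd, "noise_sd", min = 0,
                             open_min = TRUE),
    detection_fail_rate = assert_number(detection_fail_rate,
                                        "detection_fail_rate", 0, 1),
    baseline_range = baseline_range,
    seed = assert_count(seed, "seed", min = 0L)
  ), class = "gen_config")
}

# Compute Z-ratios (per contrast compartment) of the synthetic matrices for
# a candidate effect offset `delta`; used by the post-hoc calibration that
# matches the realized mean |Z-ratio| of planted genes to the requested
# effect_size.
.realized_mean_absz <- function(delta, base, noise, sign_vec, affected,
                                test_cols, ref_cols) {
  x <- base + noise
  x[, test_cols] <- x[, test_cols] + affected * sign_vec * delta
  z <- zscore_normalize(x)
  zr <- zratio_core(z, test_cols, ref_cols)$z_ratio
  mean(abs(zr[affected == 1]))
}

#' Generate a paired translatome/transcriptome study with planted truth
#'
#' Intensities are log10-normal: a per-gene baseline drawn uniformly from
#' `baseline_range` plus i.i.d. Gaussian noise of SD `noise_sd`. Regulated
#' genes receive an additive log10 offset (random sign) in the test
#' group(s): `tl_only` genes in the TL compartment only, `tr_only` in TR
#' only, `both` in both. The offset is calibrated per generation by root
#' finding so the realized mean |Z-ratio| of planted genes matches
#' `effect_size`. Detection p-values are uniform on `[0, 0.02]` for
#' detected observations and on `(0.02, 1]` for failures, drawn with
#' probability `detection_fail_rate`.
#'
#' @param cfg A [gen_config()].
#' @return A list with `study` (an [expression_study()] covering both
#'   compartments) and `truth` (data frame `gene_id`, `class`, `direction`).
#' @export
#' @examples
#' sim <- gen_expression(gen_config(n_genes = 500, seed = 7))
#' table(sim$truth$class)
gen_expression <- function(cfg) {
  stopifnot(inherits(cfg, "gen_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_genes
    genes <- sprintf("gene_%05d", seq_len(n))
    classes <- sample(names(cfg$class_fractions), n, replace = TRUE,
                      prob = cfg$class_fractions)
    sign_vec <- sample(c(-1, 1), n, replace = TRUE)
    sign_vec[classes == "null"] <- 0
    base <- stats::runif(n, cfg$baseline_range[1], cfg$baseline_range[2])

    groups <- cfg$groups
    n_reps <- cfg$n_reps
    meta <- expand.grid(replicate = seq_len(n_reps),
                        compartment = c("TL", "TR"),
                        group = groups,
                        stringsAsFactors = FALSE)
    meta <- meta[, c("group", "compartment", "replicate")]
    meta$sample_id <- sprintf("%s_%s_%d", meta$group, meta$compartment,
                              meta$replicate)
    n_samp <- nrow(meta)

    noise <- matrix(stats::rnorm(n * n_samp, 0, cfg$noise_sd), n, n_samp)
    base_mat <- matrix(base, n, n_samp)

    affects <- function(compartment) {
      as.numeric(classes == "both" |
                   classes == (if (compartment == "TL") "tl_only"
                               else "tr_only"))
    }
    test_groups <- groups[-1L]

    # Calibrate the additive log10 offset so the planted genes' realized
    # mean |Z-ratio| matches effect_size (averaged over compartments and
    # test groups). Saturates with a warning when the target exceeds what
    # the planted fraction admits.
    delta <- 0
    any_planted <- any(classes != "null")
    if (cfg$effect_size > 0 && any_planted) {
      objective <- function(d) {
        vals <- unlist(lapply(c("TL", "TR"), function(comp) {
          aff <- affects(comp)
          if (!any(aff > 0)) return(NULL)
          ref_cols <- which(meta$group == groups[1L] &
                              meta$compartment == comp)
          vapply(test_groups, function(g) {
            test_cols <- which(meta$group == g & meta$compartment == comp)
            cols <- c(test_cols, ref_cols)
            .realized_mean_absz(d, base_mat[, cols], noise[, cols], sign_vec,
                                aff, seq_along(test_cols),
                                length(test_cols) + seq_along(ref_cols))
          }, numeric(1))
        }))
        mean(vals) - cfg$effect_size
      }
      delta_max <- 25
      # realized |Z-ratio| is non-monotone in the offset (large offsets
      # inflate the column SD and the across-gene spread faster than the
      # planted signal); find the peak first, then root-find below it
      peak <- stats::optimize(objective, c(0, delta_max), maximum = TRUE,
                              tol = 1e-3)
      if (peak$objective < 0) {
        warning(sprintf(
          "effect_size %.2f exceeds what the planted fraction admits; realized mean |Z-ratio| saturates at %.2f",
          cfg$effect_size, peak$objective + cfg$effect_size),
          call. = FALSE)
        delta <- peak$maximum
      } else {
        delta <- stats::uniroot(objective, c(0, peak$maximum),
                                tol = 1e-4)$root
      }
    }

    x <- base_mat + noise
    for (comp in c("TL", "TR")) {
      aff <- affects(comp)
      for (g in test_groups) {
        cols <- which(meta$group == g & meta$compartment == comp)
        x[, cols] <- x[, cols] + aff * sign_vec * delta
      }
    }

    fail <- matrix(stats::runif(n * n_samp) < cfg$detection_fail_rate,
                   n, n_samp)
    det <- matrix(stats::runif(n * n_samp, 0, 0.02), n, n_samp)
    det[fail] <- stats::runif(sum(fail), 0.02, 1)

    dimnames(x) <- list(genes, meta$sample_id)
    dimnames(det) <- dimnames(x)
    study <- expression_study(x, det, meta[, c("sample_id", "group",
                                               "compartment", "replicate")])
    truth <- data.frame(gene_id = genes, class = classes,
                        direction = ifelse(sign_vec > 0, "+",
                                           ifelse(sign_vec < 0, "-", "0")),
                        stringsAsFactors = FALSE)
    list(study = study, truth = truth, effect_offset_log10 = delta)
  })
}

#' Generate 5'-UTR sequences with a planted motif
#'
#' Background sequences are i.i.d. nucleotides at the configured GC content.
#' Each target sequence carries, with probability `plant_rate`, one copy of
#' `motif` starting at a uniformly drawn offset inside `window` (clipped so
#' the motif fits in the sequence). Position 1 of every sequence is the TSS.
#'
#' @param n_target,n_background Number of target and background genes; the
#'   universe is their union.
#' @param motif DNA string over ACGT, length 1-20.
#' @param plant_rate Planting probability per target sequence, in `[0, 1]`.
#' @param window Half-open, 0-based interval `c(from, to)` of allowed motif
#'   start offsets from the TSS (default `c(0, 200)`).
#' @param utr_length Sequence length in nt (default 150, a median-scale
#'   human 5'-UTR); may be shorter than the window.
#' @param gc GC content of the random background (default 0.5).
#' @param seed Integer seed.
#' @return A list with `utrs` (named `DNAStringSet`), `targets`,
#'   `background` and `universe` (gene-id vectors).
#' @export
gen_utrs <- function(n_target, n_background, motif, plant_rate,
                     window = c(0, 200), utr_length = 150L, gc = 0.5,
                     seed = 1L) {
  n_target <- assert_count(n_target, "n_target")
  n_background <- assert_count(n_background, "n_background", min = 0L)
  if (!is.character(motif) || length(motif) != 1L || nchar(motif) < 1L ||
      nchar(motif) > 20L || grepl("[^ACGT]", motif)) {
    stop("'motif' must be a non-empty ACGT string of length <= 20",
         call. = FALSE)
  }
  plant_rate <- assert_number(plant_rate, "plant_rate", 0, 1)
  utr_length <- assert_count(utr_length, "utr_length",
                             min = nchar(motif))
  gc <- assert_number(gc, "gc", 0, 1, open_min = TRUE, open_max = TRUE)
  with_seed(seed, {
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    rand_seq <- function(k) {
      paste(sample(names(probs), k, replace = TRUE, prob = probs),
            collapse = "")
    }
    k <- nchar(motif)
    # motif must both start inside the window and fit in the sequence
    max_start0 <- min(window[2] - 1L, utr_length - k)
    if (max_start0 < window[1]) {
      stop("window admits no motif start that fits in the sequence",
           call. = FALSE)
    }
    tg_ids <- sprintf("target_%04d", seq_len(n_target))
    bg_ids <- if (n_background > 0L) {
      sprintf("bg_%04d", seq_len(n_background))
    } else character(0)
    seqs <- vapply(seq_len(n_target + n_background), function(i) rand_seq(utr_length),
                   character(1))
    planted <- stats::runif(n_target) < plant_rate
    for (i in which(planted)) {
      s0 <- sample(seq.int(window[1], max_start0), 1L)  # 0-based start
      substr(seqs[i], s0 + 1L, s0 + k) <- motif
    }
    utrs <- Biostrings::DNAStringSet(seqs)
    names(utrs) <- c(tg_ids, bg_ids)
    list(utrs = utrs, targets = tg_ids, background = bg_ids,
         universe = c(tg_ids, bg_ids))
  })
}

#' Generate per-fraction qPCR Ct tables for a sucrose gradient
#'
#' Simulates a monosome-plus-polysome profile over `n_fractions` fractions:
#' a light monosome peak and a broad heavy polysome mass (or a flat profile
#' with `shape = "uniform"`). `shift` moves the stated share of total mass
#' into the heavy fractions (#9-11 of 11 by default). Target Ct values
#' encode the per-fraction quantity at perfect doubling per cycle
#' (efficiency 2, matching the quantification default); the spiked
#' luciferase Ct varies per fraction and replicate to emulate RNA-recovery
#' differences, which normalization must cancel.
#'
#' @param n_fractions Number of fractions (default 11).
#' @param shape `"mixture"` (default) or `"uniform"`.
#' @param shift Heavy-share delta in `[-1, 1]`: the generated profile's
#'   heavy-fraction share equals the base profile's share plus `shift`
#'   (default 0).
#' @param n_reps Replicates (default 3).
#' @param heavy_set Fraction indices counted as heavy (default `9:11`).
#' @param ct_noise_sd Gaussian measurement noise on each Ct (default 0.05;
#'   0 gives exact profiles).
#' @param seed Integer seed.
#' @return Data frame with columns `fraction`, `replicate`, `target_ct`,
#'   `spike_ct`.
#' @export
gen_fractions <- function(n_fractions = 11L, shape = c("mixture", "uniform"),
                          shift = 0, n_reps = 3L, heavy_set = 9:11,
                          ct_noise_sd = 0.05, seed = 1L) {
  n_fractions <- assert_count(n_fractions, "n_fractions", min = 2L)
  shape <- match.arg(shape)
  shift <- assert_number(shift, "shift", -1, 1)
  n_reps <- assert_count(n_reps, "n_reps", min = 1L)
  ct_noise_sd <- assert_number(ct_noise_sd, "ct_noise_sd", min = 0)
  if (any(heavy_set < 1) || any(heavy_set > n_fractions)) {
    stop("'heavy_set' outside fraction range", call. = FALSE)
  }
  f <- seq_len(n_fractions)
  p <- if (shape == "uniform") {
    rep.int(1 / n_fractions, n_fractions)
  } else {
    mono <- stats::dnorm(f, mean = 3, sd = 1)
    poly <- stats::dnorm(f, mean = 8.5, sd = 1.8)
    m <- 0.45 * mono / sum(mono) + 0.55 * poly / sum(poly)
    m / sum(m)
  }
  if (shift != 0) {
    h0 <- sum(p[heavy_set])
    h1 <- h0 + shift
    if (h1 <= 0 || h1 >= 1) {
      stop("'shift' pushes the heavy share outside (0, 1)", call. = FALSE)
    }
    p[heavy_set] <- p[heavy_set] * h1 / h0
    p[-heavy_set] <- p[-heavy_set] * (1 - h1) / (1 - h0)
  }
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(n_reps), function(r) {
      recovery <- stats::rnorm(n_fractions, 0, 1)  # per-fraction recovery
      spike <- 20 + recovery + stats::rnorm(n_fractions, 0, ct_noise_sd)
      target <- spike - log2(p * 100) +
        stats::rnorm(n_fractions, 0, ct_noise_sd)
      data.frame(fraction = f, replicate = r, target_ct = target,
                 spike_ct = spike)
    }))
    rownames(out) <- NULL
    out
  })
}

#' Generate a first-order decay time course
#'
#' Abundance follows `2^(-t / half_life)` with multiplicative lognormal
#' noise of coefficient of variation `cv` (mean-one, so `cv = 0` gives the
#' exact exponential series), replicated `n_reps` times.
#'
#' @param half_life Half-life in hours (> 0). The package's documented
#'   default of 4.5 h is the reported half-life of the eIF4E1 protein under
#'   cycloheximide chase.
#' @param times Time points in hours, must include 0 and be non-negative.
#' @param cv Noise coefficient of variation (default 0.1).
#' @param n_reps Replicates per time point (default 3).
#' @param seed Integer seed.
#' @return Data frame with columns `time_h`, `replicate`, `abundance`.
#' @export
#' @examples
#' gen_decay(half_life = 2, times = c(0, 2, 4), cv = 0, n_reps = 1)
gen_decay <- function(half_life = 4.5, times = c(0, 2, 4, 6, 8), cv = 0.1,
                      n_reps = 3L, seed = 1L) {
  half_life <- assert_number(half_life, "half_life", min = 0,
                             open_min = TRUE)
  if (any(times < 0)) stop("'times' must be non-negative", call. = FALSE)
  if (!0 %in% times) stop("'times' must include 0", call. = FALSE)
  cv <- assert_number(cv, "cv", min = 0)
  n_reps <- assert_count(n_reps, "n_reps", min = 1L)
  mu <- 2^(-times / half_life)
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(n_reps), function(r) {
      noise <- if (cv > 0) {
        sdlog <- sqrt(log1p(cv^2))
        stats::rlnorm(length(times), meanlog = -sdlog^2 / 2, sdlog = sdlog)
      } else {
        rep.int(1, length(times))
      }
      data.frame(time_h = times, replicate = r, abundance = mu * noise)
    }))
    rownames(out) <- NULL
    out
  })
}
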