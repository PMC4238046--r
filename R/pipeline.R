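# End-to-end orchestration: generate (or load) every input, run each
# analysis stage, and write all outputs plus a JSON manifest recording the
# thresholds, method decisions, seeds and output checksums of the run.

#' Default pipeline configuration
#'
#' @param seed Master seed; stage seeds are derived from it.
#' @return A nested list understood by [run_pipeline()]. Override any
#'   element before passing it on.
#' @export
default_run_config <- function(seed = 1L) {
  seed <- assert_count(seed, "seed", min = 0L)
  list(
    seed = seed,
    expression = list(n_genes = 2000L, effect_size = 3),
    contrast = list(test = "E1", reference = "EV"),
    diff = list(n_permutations = 1000L),
    motif = list(n_target = 50L, n_background = 500L,
                 motif = "ATGCATGCAT", plant_rate = 0.8,
                 k_len = 10L, window = c(0L, 200L)),
    fractions = list(n_fractions = 11L, shift = 0.15, n_reps = 3L),
    decay = list(half_life = 4.5, times = c(0, 2, 4, 6, 8), cv = 0.1,
                 n_reps = 3L)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Run the full translatome-switch pipeline
#'
#' Stages, in order: synthetic-data generation, Z-ratio differential
#' analysis of the TL and TR contrasts, the switch partition with Venn
#' counts, top tables and truth confusion matrix, motif discovery on
#' planted UTRs, fraction-profile comparison, and decay fitting. All
#' outputs are TSV/JSON under `out_dir`; `manifest.json` records package
#' version, configuration, method decisions and md5 checksums of every
#' output, so reruns with the same configuration and seed are bit-identical.
#' A stage failure aborts with a stage-named error and leaves a `FAILED`
#' marker naming the stage.
#'
#' @param config A configuration list (see [default_run_config()]), a path
#'   to a YAML/JSON file of overrides, or `NULL` for the defaults.
#' @param out_dir Output directory (created).
#' @param seed Optional master seed overriding the config's.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = NULL, out_dir = "transwitch_run",
                         seed = NULL) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  cfg <- merge_config(default_run_config(), config %||% list())
  if (!is.null(seed)) cfg$seed <- assert_count(seed, "seed", min = 0L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  current_stage <- "setup"
  on_fail <- function(e) {
    writeLines(paste("stage:", current_stage, "-", conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop(sprintf("pipeline stage '%s' failed: %s", current_stage,
                 conditionMessage(e)), call. = FALSE)
  }
  emit <- function(x, name, writer = write_tsv) {
    path <- file.path(out_dir, name)
    writer(x, path)
    outputs <<- c(outputs, path)
    path
  }
  json_writer <- function(x, path) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }
  tryCatch({
    current_stage <- "synth"
    gcfg <- do.call(gen_config, c(cfg$expression, list(seed = cfg$seed)))
    sim <- gen_expression(gcfg)
    write_study(sim$study, file.path(out_dir, "study"))
    outputs <- c(outputs, file.path(out_dir, "study",
                                    c("matrix.tsv", "detection.tsv",
                                      "samples.tsv")))
    emit(sim$truth, "truth.tsv")

    current_stage <- "diff"
    params <- do.call(diff_params,
                      c(cfg$diff, list(seed = cfg$seed + 1L)))
    tl <- diff_contrast(sim$study,
                        sample_contrast(cfg$contrast$test,
                                        cfg$contrast$reference, "TL"),
                        params)
    tr <- diff_contrast(sim$study,
                        sample_contrast(cfg$contrast$test,
                                        cfg$contrast$reference, "TR"),
                        params)
    write_diff_result(tl, file.path(out_dir, "diff_TL.tsv"))
    write_diff_result(tr, file.path(out_dir, "diff_TR.tsv"))
    outputs <- c(outputs, file.path(out_dir,
                                    c("diff_TL.tsv", "diff_TL.meta.json",
                                      "diff_TR.tsv", "diff_TR.meta.json")))

    current_stage <- "switch"
    part <- partition_switch(tl, tr)
    emit(part$table, "partition.tsv")
    emit(venn_counts(part), "venn_counts.json", json_writer)
    emit(top_table(part, tl, tr, n = 50L, set = "exclusive_tl"),
         "top_exclusive_tl.tsv")
    emit(top_table(part, tl, tr, n = 50L, set = "exclusive_tr"),
         "top_exclusive_tr.tsv")
    conf <- as.data.frame.matrix(switch_confusion(part, sim$truth))
    emit(data.frame(truth = rownames(conf), conf, check.names = FALSE),
         "confusion.tsv")

    current_stage <- "motif"
    mu <- cfg$motif
    utr <- gen_utrs(mu$n_target, mu$n_background, mu$motif, mu$plant_rate,
                    window = mu$window, seed = cfg$seed + 2L)
    Biostrings::writeXStringSet(utr$utrs, file.path(out_dir, "utrs.fasta"))
    outputs <- c(outputs, file.path(out_dir, "utrs.fasta"))
    disc <- discover_motifs(utr$targets, utr$universe, utr$utrs,
                            k_len = mu$k_len, window = mu$window)
    emit(as.data.frame(disc), "motifs.tsv")
    if (nrow(disc) > 0L) {
      bias <- bias_diagnostics(utr$targets, utr$universe, utr$utrs,
                               disc$motif[1L], window = mu$window)
      emit(list(motif = bias$motif,
                gc_p = bias$gc_test$p, length_p = bias$length_test$p,
                strand_sense = bias$strand_bias$sense,
                strand_antisense = bias$strand_bias$antisense,
                strand_p = bias$strand_bias$p,
                localization_p = bias$localization$p),
           "bias_report.json", json_writer)
    }

    current_stage <- "fractions"
    fc <- cfg$fractions
    ct_a <- gen_fractions(fc$n_fractions, shift = fc$shift,
                          n_reps = fc$n_reps, seed = cfg$seed + 3L)
    ct_b <- gen_fractions(fc$n_fractions, shift = 0, n_reps = fc$n_reps,
                          seed = cfg$seed + 4L)
    ct_a$condition <- "shifted"
    ct_b$condition <- "control"
    emit(rbind(ct_a, ct_b), "fraction_cts.tsv")
    prof_a <- profiles_from_table(ct_a[, names(ct_a) != "condition"])
    prof_b <- profiles_from_table(ct_b[, names(ct_b) != "condition"])
    cmp <- compare_profiles(prof_a, prof_b)
    emit(cmp$per_fraction, "fraction_comparison.tsv")
    emit(cmp$heavy, "heavy_share.json", json_writer)

    current_stage <- "decay"
    dc <- cfg$decay
    course <- gen_decay(dc$half_life, dc$times, dc$cv, dc$n_reps,
                        seed = cfg$seed + 5L)
    emit(course, "decay_course.tsv")
    fit <- fit_decay(course$time_h, course$abundance, n_boot = 500L,
                     seed = cfg$seed + 6L)
    emit(list(half_life_h = fit$half_life, rate_per_h = fit$rate,
              r_squared = fit$r_squared,
              ci_half_life = fit$ci_half_life,
              planted_half_life_h = dc$half_life),
         "decay_fit.json", json_writer)

    current_stage <- "manifest"
    manifest <- list(
      package = "transwitch",
      version = as.character(utils::packageVersion("transwitch")),
      seed = cfg$seed,
      config = cfg,
      decisions = tl$metadata,
      outputs = as.list(stats::setNames(
        unname(tools::md5sum(sort(outputs))), basename(sort(outputs))))
    )
    json_writer(manifest, file.path(out_dir, "manifest.json"))
    invisible(manifest)
  }, error = on_fail)
}
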