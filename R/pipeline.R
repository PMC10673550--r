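#' Default pipeline configuration
#'
#' All tolerances, thresholds, study-design settings and generator
#' parameters in one place; every numeric threshold appearing in pipeline
#' outputs is traceable to this object. Per-stage seeds are derived
#' deterministically from the root seed.
#'
#' @param seed root RNG seed.
#' @param n_pairs patient pairs (default 24).
#' @param n_decoys decoy peaks in the screening fixture (default 100).
#' @param out_dir optional output directory; `NULL` skips writing.
#' @return A `pipeline_config` list.
#' @export
default_config <- function(seed = 1, n_pairs = 24, n_decoys = 100,
                           out_dir = NULL) {
  structure(list(
    seed = as.integer(seed),
    n_pairs = as.integer(n_pairs),
    n_decoys = as.integer(n_decoys),
    mz_tol = 0.3,
    rt_tol = 0.05,
    max_log2_ratio = 0.585,
    rt_match_tol = 0.05,
    fc_threshold = 1.5,
    p_threshold = 0.05,
    vip_threshold = 1.0,
    n_orthogonal = 1,
    null_sd = 0.15,
    patient_sd = 0.2,
    roc_repeats = 50,
    roc_train_fraction = 2 / 3,
    out_dir = out_dir
  ), class = "pipeline_config")
}

#' Write a config as a flat key = value file
#' @param config a `pipeline_config`.
#' @param path output file.
#' @export
write_config <- function(config, path) {
  keys <- setdiff(names(config), "out_dir")
  writeLines(paste0(keys, " = ",
                    vapply(config[keys], format, "", digits = 17)), path)
  invisible(path)
}

#' Read a config written by [write_config()]
#' @param path input file.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, " = ", fixed = TRUE)
  cfg <- default_config()
  for (p in kv) {
    cfg[[p[1]]] <- if (p[1] %in% c("seed", "n_pairs", "n_decoys",
                                   "n_orthogonal", "roc_repeats"))
      as.integer(p[2]) else as.numeric(p[2])
  }
  cfg
}

#' Run the end-to-end pipeline on synthetic study data
#'
#' Stages: generate (chromatographic screening fixture + paired abundance
#' study) -> transitions -> pair -> annotate -> quantify -> differential
#' statistics -> multivariate ROC. Identical config and seed reproduce
#' every output byte for byte. When `config$out_dir` is set, each stage's
#' table is written as tab-separated text together with a run log carrying
#' the seeds, thresholds and per-stage record counts.
#'
#' @param config a [default_config()] object.
#' @return A `pipeline_report` list: `transitions`, `pairing`
#'   (pairs/unpaired/score), `annotated`, `abundance`, `differential`
#'   (records/model/venn), `roc`, `log` (character vector).
#' @export
run_pipeline <- function(config = default_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- c(sprintf("root seed: %d", config$seed),
           sprintf("thresholds: fc %.2f, p %.3f, vip %.1f, mz_tol %.2f, rt_tol %.3f, ratio band %.3f",
                   config$fc_threshold, config$p_threshold,
                   config$vip_threshold, config$mz_tol, config$rt_tol,
                   config$max_log2_ratio))

  panel <- fahfa_panel()
  transitions <- panel_transitions(panel, nominal = TRUE)
  log <- c(log, sprintf("transitions: %d rows (%d species)",
                        nrow(transitions), nrow(panel)))

  fixture <- generate_chrom_fixture(
    chrom_fixture_spec(panel = panel, n_decoys = config$n_decoys,
                       seed = stage_seed(config$seed, "chrom")),
    mz_tol = config$mz_tol, rt_tol = config$rt_tol
  )
  pairing <- pair_peaks(fixture$light, fixture$heavy, config$mz_tol,
                        config$rt_tol, config$max_log2_ratio)
  pairing$score <- score_pairs(pairing$pairs, fixture$truth)
  log <- c(log, sprintf("pairing: %d pairs, %d unpaired (recall %.3f, %d decoys admitted)",
                        nrow(pairing$pairs), nrow(pairing$unpaired),
                        pairing$score$recall, pairing$score$n_decoy_pairs))

  screening_tr <- transitions[transitions$channel_kind == "LOSS_FA_63", ]
  pairs_fam <- assign_families(pairing$pairs, screening_tr, config$mz_tol)
  maxp <- vapply(.FAMILY_DEFS, function(d) d$hfa - 1, 0)
  annotated <- annotate_pairs(pairs_fam, fahfa_standards(),
                              rt_match_tol = config$rt_match_tol,
                              max_positions = maxp)
  log <- c(log, sprintf("annotation: %d/%d pairs positioned (%d by standard, %d by regression)",
                        sum(!is.na(annotated$position)), nrow(annotated),
                        sum(annotated$method == "STANDARD_MATCH", na.rm = TRUE),
                        sum(annotated$method == "RI_REGRESSION", na.rm = TRUE)))

  design <- study_design(config$n_pairs, seed = config$seed)
  effects <- study_effects(config$n_pairs, null_sd = config$null_sd)
  truth_ab <- generate_abundance_study(
    design, effects, patient_sd = config$patient_sd,
    seed = stage_seed(config$seed, "abundance"))
  peaks <- simulate_sample_heights(truth_ab)
  abundance <- build_abundance_matrix(peaks, design$samples,
                                      analytes = truth_ab$analytes)
  log <- c(log, sprintf("quantification: %d analytes x %d samples",
                        nrow(abundance$values), ncol(abundance$values)))

  differential <- run_differential(
    abundance, fc_threshold = config$fc_threshold,
    p_threshold = config$p_threshold, vip_threshold = config$vip_threshold,
    n_orthogonal = config$n_orthogonal,
    seed = stage_seed(config$seed, "cv"))
  log <- c(log, sprintf("differential: %d in venn set (%d up, %d down); R2Y %.3f Q2 %.3f",
                        nrow(differential$venn),
                        sum(differential$venn$regulation == "UP"),
                        sum(differential$venn$regulation == "DOWN"),
                        differential$model$r2y, differential$model$q2))

  pp <- preprocess(abundance)
  panel_ids <- intersect(differential$venn$analyte_id, rownames(pp$z))
  roc <- if (length(panel_ids) >= 1) {
    mccv_auc(pp$z, abundance$samples$group, method = "RF",
             features = panel_ids, n_repeats = config$roc_repeats,
             train_fraction = config$roc_train_fraction,
             seed = stage_seed(config$seed, "roc"))
  } else NULL
  if (!is.null(roc)) {
    log <- c(log, sprintf("roc: RF AUC %.3f [%.3f, %.3f] on %d analytes",
                          roc$auc, roc$auc_ci[1], roc$auc_ci[2],
                          length(panel_ids)))
  }

  report <- structure(
    list(transitions = transitions, fixture = fixture, pairing = pairing,
         annotated = annotated, abundance = abundance,
         differential = differential, roc = roc, config = config,
         log = log),
    class = "pipeline_report"
  )
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("CIL-LC-MS pipeline report\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  invisible(x)
}

#' Write a pipeline report's tables under a directory
#' @param report a `pipeline_report`.
#' @param dir output directory (created if needed).
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(report$transitions, file.path(dir, "transitions.tsv"))
  write_tsv(report$annotated, file.path(dir, "pairs_annotated.tsv"))
  ab <- report$abundance
  mat <- data.frame(analyte_id = rownames(ab$values), ab$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(mat, file.path(dir, "abundance_matrix.tsv"))
  write_tsv(ab$samples, file.path(dir, "samples.tsv"))
  write_tsv(report$differential$records, file.path(dir, "differential.tsv"))
  if (!is.null(report$roc)) {
    write_tsv(data.frame(method = report$roc$method, auc = report$roc$auc,
                         ci_lo = report$roc$auc_ci[1],
                         ci_hi = report$roc$auc_ci[2],
                         n_repeats = report$roc$n_repeats),
              file.path(dir, "roc.tsv"))
  }
  write_config(report$config, file.path(dir, "config.txt"))
  writeLines(report$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}
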