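# End-to-end pipeline: simulate -> cross-omics discovery -> clonality ->
# biomarker evaluation -> cohort modelling, with every stage seeded from the
# single global seed, all tables written as TSV, models and reports as JSON,
# and a run log recording seeds, parameters and input hashes.

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Run the full analysis pipeline from a configuration
#'
#' Stages: `simulate` (generate paired omics, clonality profiles and a
#' cohort), `crossomics` (per-layer differential expression, cross-layer
#' correlation, candidate selection), `clonality` (scores, group comparison,
#' score-marker correlation), `evaluate` (ROC, Youden and minimal-AIC
#' cutoffs, spline linearity test on the matched cohort), `model`
#' (propensity matching, derivation/validation split, AIC-guided model,
#' nomogram, calibration). Outputs are deterministic given the configuration;
#' timestamps are confined to the log file.
#'
#' @param config configuration list (see [read_pipeline_config()]); `seed`
#'   and `outdir` are required.
#' @param seed optional override of `config$seed`.
#' @param outdir optional override of `config$outdir`.
#' @return invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(config = list(), seed = NULL, outdir = NULL) {
  seed <- as.integer(seed %||% config$seed %||% 1L)
  outdir <- outdir %||% config$outdir %||% stop("outdir required")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(outdir, "pipeline.log")
  cat(sprintf("[%s] pipeline start, seed = %d\n", Sys.time(), seed),
      file = logfile)
  log_line <- function(...) cat(sprintf(...), "\n", sep = "", file = logfile,
                                append = TRUE)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      log_line("ERROR in stage %s: %s", name, conditionMessage(e))
      stop(sprintf("pipeline stage `%s` failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  ## --- simulate ------------------------------------------------------------
  sim <- config$simulate %||% list()
  omics_cfg <- do.call(omics_sim_config,
                       utils::modifyList(list(seed = substream_seed(seed, 1L)),
                                         sim$omics %||% list()))
  cohort_cfg <- do.call(cohort_sim_config,
                        utils::modifyList(list(seed = substream_seed(seed, 2L)),
                                          sim$cohort %||% list()))
  clon_cfg <- do.call(clonality_sim_config,
                      utils::modifyList(list(seed = substream_seed(seed, 3L)),
                                        sim$clonality %||% list()))
  run_stage("simulate", {
    paired <- generate_paired_omics(omics_cfg)
    cohort <- generate_cohort(cohort_cfg)
    clon <- generate_clonality(clon_cfg)
  })
  write_expression_matrix(paired$proteome, file.path(outdir, "proteome.tsv"))
  write_expression_matrix(paired$transcriptome,
                          file.path(outdir, "transcriptome.tsv"))
  .write_tsv(paired$pair_map, file.path(outdir, "pair_map.tsv"))
  write_cohort(cohort, file.path(outdir, "cohort.tsv"))
  .write_tsv(clon, file.path(outdir, "clonality_abundances.tsv"))
  .write_json(list(planted = paired$planted,
                   omics_seed = omics_cfg$seed,
                   cohort_seed = cohort_cfg$seed,
                   clonality_seed = clon_cfg$seed),
              file.path(outdir, "planted_truth.json"))
  log_line("simulate: %d pairs, %d patients, %d clonality subjects",
           nrow(paired$pair_map), nrow(cohort), nrow(clon))

  ## --- crossomics ----------------------------------------------------------
  co <- config$crossomics %||% list()
  thr <- selection_thresholds(
    prot_log2fc_min = co$prot_log2fc_min %||% log2(1.2),
    trans_log2fc_min = co$trans_log2fc_min %||% log2(1.5),
    alpha_de = co$alpha_de %||% 0.05,
    alpha_corr = co$alpha_corr %||% 0.05,
    adjust_corr = co$adjust_corr %||% FALSE,
    require_concordant_direction = co$require_concordant_direction %||% TRUE)
  run_stage("crossomics", {
    de_p <- differential_expression(paired$proteome,
                                     paired$case_ids$proteome,
                                     paired$control_ids$proteome)
    de_t <- differential_expression(paired$transcriptome,
                                     paired$case_ids$transcriptome,
                                     paired$control_ids$transcriptome)
    corrs <- pair_correlation(paired, min_n = co$min_n %||% 5L)
    rationale <- select_tumour_derived(de_p, de_t, corrs, thr,
                                        pair_map = paired$pair_map)
  })
  .write_tsv(de_p, file.path(outdir, "de_proteome.tsv"))
  .write_tsv(de_t, file.path(outdir, "de_transcriptome.tsv"))
  .write_tsv(corrs, file.path(outdir, "pair_correlation.tsv"))
  .write_tsv(rationale, file.path(outdir, "candidates.tsv"))
  log_line("crossomics: %d candidates of %d pairs",
           sum(rationale$selected), nrow(rationale))

  ## --- clonality -----------------------------------------------------------
  run_stage("clonality", {
    clon$score <- kappa_lambda_score(clon$kappa, clon$lambda)
    clon_tests <- compare_scores(clon$score, clon$group)
  })
  .write_tsv(clon, file.path(outdir, "clonality_scores.tsv"))
  .write_tsv(clon_tests, file.path(outdir, "clonality_tests.tsv"))
  log_line("clonality: case vs control p = %.3g", clon_tests$p_value[1])

  ## --- evaluate ------------------------------------------------------------
  ev <- config$evaluate %||% list()
  mo <- config$model %||% list()
  run_stage("evaluate", {
    covars <- mo$covariates %||% c("sex", "age_years", "date_of_diagnosis",
                                   "bilateral", "disease_site")
    psm <- propensity_match(cohort, covars,
                             cohort$diagnosis_class == "EMZL",
                             caliper = mo$caliper %||% Inf)
    mcoh <- matched_cohort(cohort, psm)
    roc <- roc_curve(mcoh$igm_g_per_l, mcoh$diagnosis_class == "EMZL",
                      boot = ev$boot %||% 2000L,
                      seed = substream_seed(seed, 4L))
    yc <- youden_cutoff(roc, strategy = ev$cutoff_strategy %||% "youden")
    rcs <- nonlinearity_test(mcoh$igm_g_per_l,
                              mcoh$diagnosis_class == "EMZL",
                              knots = default_knots(mcoh$igm_g_per_l,
                                                    ev$n_knots %||% 4L))
    scan <- aic_cutoff_scan(mcoh$igm_g_per_l,
                             mcoh$diagnosis_class == "EMZL")
    agec <- age_cutoff(cohort)
  })
  .write_tsv(data.frame(threshold = roc$thresholds,
                        sensitivity = roc$sensitivity,
                        specificity = roc$specificity),
             file.path(outdir, "roc_igm_matched.tsv"))
  .write_json(list(
    auc = roc$auc, auc_ci = roc$auc_ci,
    roc_cutoff = yc$cutoff, roc_sensitivity = yc$sensitivity,
    roc_specificity = yc$specificity,
    aic_cutoff = scan$aic_cutoff, aic_value = scan$aic_value,
    age_cutoff = agec$cutoff,
    p_nonlinearity_igm = rcs$p_nonlinearity,
    knots = rcs$knots), file.path(outdir, "cutoffs.json"))
  .write_json(list(knots = rcs$knots,
                   coefficients = as.list(rcs$coefficients),
                   log_likelihood = rcs$log_likelihood, aic = rcs$aic,
                   p_nonlinearity = rcs$p_nonlinearity),
              file.path(outdir, "rcs_fit.json"))
  .write_tsv(data.frame(covariate = names(psm$smd_before),
                        smd_before = psm$smd_before,
                        smd_after = psm$smd_after),
             file.path(outdir, "psm_balance.tsv"))
  log_line("evaluate: AUC %.3f, ROC cutoff %.3f, AIC cutoff %.3f",
           roc$auc, yc$cutoff, scan$aic_cutoff)

  ## --- model ---------------------------------------------------------------
  run_stage("model", {
    low_cut <- min(scan$aic_cutoff, yc$cutoff)
    high_cut <- max(scan$aic_cutoff, yc$cutoff)
    if (low_cut >= high_cut) { low_cut <- high_cut * 0.6 }
    val <- split_and_validate(cohort, low_cut, high_cut, agec$cutoff,
                               derivation_fraction = mo$derivation_fraction %||% 0.6,
                               seed = substream_seed(seed, 5L))
    calib <- calibration_assess(val$selection$fit,
                                 n_bins = mo$calibration_bins %||% 10L,
                                 bootstrap_reps = mo$calibration_boot %||% 200L,
                                 seed = substream_seed(seed, 6L))
  })
  fit <- val$selection$fit
  .write_json(list(
    terms = as.list(fit$terms), se = as.list(fit$se),
    p_values = as.list(fit$p_values), aic = fit$aic,
    log_likelihood = fit$log_likelihood,
    included_candidates = val$selection$included,
    nomogram = list(
      points_per_term = lapply(val$nomogram$points_per_term, function(t)
        if (is.data.frame(t)) as.list(t) else t),
      scale = val$nomogram$scale, offset = val$nomogram$offset)),
    file.path(outdir, "model.json"))
  .write_tsv(val$aucs, file.path(outdir, "validation_aucs.tsv"))
  .write_tsv(calib, file.path(outdir, "calibration.tsv"))
  log_line("model: derivation AUC %.3f, validation AUC %.3f",
           val$aucs$model_auc[1],
           if (nrow(val$aucs) > 1) val$aucs$model_auc[2] else NA)

  ## --- log hashes ----------------------------------------------------------
  outs <- setdiff(list.files(outdir, full.names = TRUE), logfile)
  h <- tools::md5sum(outs)
  for (i in seq_along(h)) log_line("md5 %s %s", h[i], basename(outs[i]))
  log_line("[%s] pipeline done", Sys.time())

  invisible(list(paired = paired, cohort = cohort, clonality = clon,
                 de_proteome = de_p, de_transcriptome = de_t,
                 correlations = corrs, rationale = rationale,
                 clonality_tests = clon_tests, match = psm, roc = roc,
                 youden = yc, rcs = rcs, aic_scan = scan,
                 age_cutoff = agec, validation = val, calibration = calib))
}
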