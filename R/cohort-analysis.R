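# Clinical cohort analyses: per-contrast group comparisons, the
# post-vs-pre-treatment marker change, confounder screening, the ROC-derived
# age cutoff, the stratified derivation/validation split with nomogram
# validation, and bootstrap calibration assessment.

#' Rank-sum group comparisons of a marker with BH adjustment
#'
#' Two-sided Wilcoxon rank-sum per contrast (default: cases vs each control
#' class), Benjamini-Hochberg adjusted across the contrasts.
#'
#' @param cohort data.frame with `diagnosis_class` and the value column.
#' @param value_col name of the numeric column to compare.
#' @param contrasts list of 2-vectors of diagnosis classes; default EMZL vs
#'   each other class present.
#' @return data.frame with one row per contrast and a `q_value` column.
#' @export
group_tests <- function(cohort, value_col = "igm_g_per_l", contrasts = NULL) {
  res <- compare_scores(cohort[[value_col]], cohort$diagnosis_class, contrasts)
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res
}

#' Post-minus-pre treatment change analysis
#'
#' For subjects with a post-treatment value, computes `delta = post - pre`,
#' tests it against zero within each diagnosis class (two-sided Wilcoxon
#' signed-rank) and compares deltas between classes (rank-sum).
#'
#' @param cohort data.frame with `igm_g_per_l`, `igm_post_treatment`,
#'   `diagnosis_class`.
#' @param contrasts between-group contrasts on delta; default: classes with
#'   data vs each other.
#' @return list with `per_group` (one-sample results) and `between`
#'   (rank-sum results), plus `deltas`.
#' @export
delta_igm_analysis <- function(cohort, contrasts = NULL) {
  has <- !is.na(cohort$igm_post_treatment)
  if (!any(has)) stop("no post-treatment values present", call. = FALSE)
  d <- cohort$igm_post_treatment[has] - cohort$igm_g_per_l[has]
  grp <- as.character(cohort$diagnosis_class[has])
  per_group <- do.call(rbind, lapply(unique(grp), function(g) {
    dd <- d[grp == g]
    if (all(dd == 0)) {
      p <- 1; v <- 0
    } else {
      wt <- suppressWarnings(stats::wilcox.test(dd, mu = 0))
      p <- wt$p.value; v <- unname(wt$statistic)
    }
    data.frame(group = g, n = length(dd), median_delta = stats::median(dd),
               statistic = v, p_value = p, stringsAsFactors = FALSE)
  }))
  between <- if (length(unique(grp)) > 1)
    compare_scores(d, grp, contrasts) else NULL
  list(per_group = per_group, between = between,
       deltas = data.frame(subject_id = cohort$subject_id[has],
                           group = grp, delta = d, stringsAsFactors = FALSE))
}

#' Screen age and sex as confounders of the marker
#'
#' Per diagnosis class: Spearman correlation of the marker with age, and a
#' rank-sum comparison of the marker between sexes.
#'
#' @param cohort data.frame with `igm_g_per_l`, `age_years`, `sex`,
#'   `diagnosis_class`.
#' @param value_col marker column (default `igm_g_per_l`).
#' @param min_n minimum subjects per class for a correlation.
#' @return list with `age_correlation` and `sex_comparison` data.frames.
#' @export
confounder_screen <- function(cohort, value_col = "igm_g_per_l", min_n = 5L) {
  v <- cohort[[value_col]]
  age_cor <- per_group_correlation(v, cohort$age_years,
                                   cohort$diagnosis_class, min_n = min_n)
  names(age_cor)[1] <- "group"
  sex_cmp <- do.call(rbind, lapply(unique(as.character(cohort$diagnosis_class)),
                                   function(g) {
    sel <- cohort$diagnosis_class == g
    x <- v[sel & cohort$sex == levels(factor(cohort$sex))[1]]
    y <- v[sel & cohort$sex != levels(factor(cohort$sex))[1]]
    if (length(x) < 2 || length(y) < 2)
      return(data.frame(group = g, p_value = NA_real_, stringsAsFactors = FALSE))
    data.frame(group = g,
               p_value = suppressWarnings(stats::wilcox.test(x, y)$p.value),
               stringsAsFactors = FALSE)
  }))
  list(age_correlation = age_cor, sex_comparison = sex_cmp)
}

#' ROC-derived age cutoff
#'
#' Younger age is the case-like direction in this disease setting, so the ROC
#' is computed on the negated age and the Youden threshold mapped back to
#' years. Returns the cutoff and the per-subject indicator `age < cutoff`.
#'
#' @param cohort data.frame with `age_years` and `diagnosis_class`.
#' @param case_class the case diagnosis class (default `"EMZL"`).
#' @return list with `cutoff` (years), `sensitivity`, `specificity`,
#'   `indicator` (logical `age < cutoff`), `roc`.
#' @export
age_cutoff <- function(cohort, case_class = "EMZL") {
  is_case <- cohort$diagnosis_class == case_class
  roc <- roc_curve(-cohort$age_years, is_case, boot = 0L)
  yc <- youden_cutoff(roc)
  thr_age <- -yc$cutoff                      # ages <= thr_age are case-like
  above <- cohort$age_years[cohort$age_years > thr_age]
  # report the midpoint to the next observed age so that the strict
  # `age < cutoff` indicator reproduces the selected dichotomy exactly
  cutoff <- if (length(above)) (thr_age + min(above)) / 2 else thr_age + 1
  list(cutoff = cutoff, sensitivity = yc$sensitivity,
       specificity = yc$specificity,
       indicator = cohort$age_years < cutoff, roc = roc)
}

# largest-remainder stratified allocation of round(frac * N) slots
.stratified_split <- function(classes, frac, seed) {
  set.seed(substream_seed(seed, 53L))
  n <- length(classes)
  target_total <- round(frac * n)
  lv <- unique(as.character(classes))
  quota <- vapply(lv, function(g) frac * sum(classes == g), numeric(1))
  base <- floor(quota)
  rem <- target_total - sum(base)
  if (rem > 0) {
    extra <- order(-(quota - base))[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  deriv <- logical(n)
  for (k in seq_along(lv)) {
    idx <- which(classes == lv[k])
    take <- idx[sample.int(length(idx), min(base[k], length(idx)))]
    deriv[take] <- TRUE
  }
  deriv
}

#' Build the diagnostic-model design columns for a cohort
#'
#' Adds the ordinal-marker dummies (`igm_mid`, `igm_high`), the age indicator
#' (`age_lt_cutoff`), the lacrimal-involvement indicator and the case outcome
#' to a cohort table.
#'
#' @param cohort cohort data.frame.
#' @param low_cut,high_cut ordinal marker boundaries in g/L.
#' @param age_cut age cutoff in years.
#' @param case_class case diagnosis class.
#' @return the cohort with columns `igm_mid`, `igm_high`, `age_lt_cutoff`,
#'   `lacrimal`, `is_case` appended.
#' @export
model_frame <- function(cohort, low_cut, high_cut, age_cut,
                        case_class = "EMZL") {
  o <- ordinalize(cohort$igm_g_per_l, low_cut, high_cut)
  cohort$igm_mid <- o$mid
  cohort$igm_high <- o$high
  cohort$age_lt_cutoff <- as.integer(cohort$age_years < age_cut)
  cohort$lacrimal <- as.integer(cohort$lacrimal_involvement)
  cohort$is_case <- as.integer(cohort$diagnosis_class == case_class)
  cohort
}

#' Stratified derivation/validation split with model validation
#'
#' Splits the cohort by diagnosis class (largest-remainder allocation, seeded
#' shuffle within class, class proportions preserved within one subject), fits
#' the diagnostic model on the derivation set — base terms: ordinal-marker
#' dummies and the age indicator; candidate: lacrimal involvement, included
#' if it lowers the AIC — and evaluates the model score against the
#' continuous and ordinal marker by ROC on both sets.
#'
#' @param cohort cohort data.frame.
#' @param low_cut,high_cut,age_cut cutoffs for [model_frame()].
#' @param derivation_fraction fraction assigned to the derivation set
#'   (default 0.6).
#' @param seed integer seed for the split and bootstrap.
#' @param boot bootstrap resamples for the AUC CIs (0 = none).
#' @return list with `selection` (the [select_model()] output), `nomogram`,
#'   `split` (logical derivation indicator), `aucs` (data.frame of model /
#'   continuous / ordinal AUC on each set), `derivation`, `validation`
#'   (the model frames).
#' @export
split_and_validate <- function(cohort, low_cut, high_cut, age_cut,
                               derivation_fraction = 0.6, seed = 1L,
                               boot = 0L) {
  if (derivation_fraction <= 0 || derivation_fraction > 1)
    stop("derivation_fraction must be in (0, 1]", call. = FALSE)
  mf <- model_frame(cohort, low_cut, high_cut, age_cut)
  deriv <- .stratified_split(mf$diagnosis_class, derivation_fraction, seed)
  dtrain <- mf[deriv, , drop = FALSE]
  dtest <- mf[!deriv, , drop = FALSE]
  if (!nrow(dtest))
    warning("validation set is empty (derivation_fraction = ",
            derivation_fraction, ")")

  sel <- select_model(dtrain, "is_case",
                      base_terms = c("igm_mid", "igm_high", "age_lt_cutoff"),
                      candidate_terms = "lacrimal")
  nom <- build_nomogram(sel$fit)

  score_design <- function(d) {
    X <- cbind(`(Intercept)` = 1,
               as.matrix(as.data.frame(
                 lapply(d[names(sel$fit$terms)[-1]], as.numeric))))
    colnames(X) <- names(sel$fit$terms)
    X
  }
  auc_row <- function(d, set) {
    if (!nrow(d) || length(unique(d$is_case)) < 2)
      return(NULL)
    sc <- predict(sel$fit, score_design(d))
    data.frame(
      set = set,
      model_auc = roc_curve(sc, d$is_case, boot = 0L)$auc,
      continuous_auc = roc_curve(d$igm_g_per_l, d$is_case, boot = 0L)$auc,
      ordinal_auc = roc_curve(d$igm_mid + 2 * d$igm_high, d$is_case,
                              boot = 0L)$auc,
      stringsAsFactors = FALSE)
  }
  aucs <- rbind(auc_row(dtrain, "derivation"), auc_row(dtest, "validation"))
  list(selection = sel, nomogram = nom, split = deriv, aucs = aucs,
       derivation = dtrain, validation = dtest)
}

#' Calibration of a fitted logistic model
#'
#' Bins subjects into `n_bins` equal-count bins of predicted probability and
#' compares the observed case frequency with the mean prediction per bin.
#' With `bootstrap_reps > 0`, an optimism-corrected observed frequency is
#' estimated by refitting on bootstrap resamples (Harrell's optimism
#' bootstrap applied bin-wise).
#'
#' @param fit a [fit_logistic()] result (stores its design and outcome).
#' @param n_bins number of equal-count bins (default 10).
#' @param bootstrap_reps bootstrap refits for optimism correction (default 0).
#' @param seed integer seed for the bootstrap.
#' @return data.frame with `bin`, `n`, `mean_predicted`, `observed`, and
#'   (when bootstrapped) `observed_corrected`.
#' @export
calibration_assess <- function(fit, n_bins = 10L, bootstrap_reps = 0L,
                               seed = 1L) {
  stopifnot(inherits(fit, "logistic_fit"))
  p <- fit$fitted
  y <- fit$outcome
  n_bins <- max(1L, min(n_bins, length(unique(p))))
  br <- unique(stats::quantile(p, probs = seq(0, 1, length.out = n_bins + 1),
                               type = 7))
  bin <- cut(p, breaks = br, include.lowest = TRUE, labels = FALSE)
  tab <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    sel <- bin == b
    data.frame(bin = b, n = sum(sel), mean_predicted = mean(p[sel]),
               observed = mean(y[sel]))
  }))
  if (bootstrap_reps > 0) {
    set.seed(substream_seed(seed, 71L))
    X <- fit$design
    optimism <- matrix(0, nrow = nrow(tab), ncol = bootstrap_reps)
    for (b in seq_len(bootstrap_reps)) {
      idx <- sample.int(nrow(X), replace = TRUE)
      bf <- tryCatch(fit_logistic(X[idx, , drop = FALSE], y[idx]),
                     error = function(e) NULL)
      if (is.null(bf)) next
      p_orig <- predict(bf, X)       # boot model on original data
      p_boot <- bf$fitted            # boot model on boot data
      y_boot <- y[idx]
      for (r in seq_len(nrow(tab))) {
        sel_b <- p_boot > br[tab$bin[r]] - 1e-12 & p_boot <= br[tab$bin[r] + 1] + 1e-12
        sel_o <- bin == tab$bin[r]
        app <- if (any(sel_b)) mean(y_boot[sel_b]) - mean(p_boot[sel_b]) else 0
        tst <- if (any(sel_o)) mean(y[sel_o]) - mean(p_orig[sel_o]) else 0
        optimism[r, b] <- app - tst
      }
    }
    tab$observed_corrected <- tab$observed - rowMeans(optimism)
  }
  tab
}
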