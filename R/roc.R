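# Empirical ROC analysis for a continuous marker. The AUC uses the
# tie-corrected rank (Mann-Whitney) formula, equivalent to pair counting with
# ties worth one half; the confidence interval is a stratified percentile
# bootstrap.

#' Empirical ROC curve with tie-corrected AUC and bootstrap CI
#'
#' Thresholds are the unique observed values plus `-Inf`/`Inf` sentinels; a
#' subject is called positive when `value >= threshold`. The AUC equals the
#' Mann-Whitney U statistic divided by `n_pos * n_neg`, counting ties as one
#' half. The CI is a stratified (class-preserving) percentile bootstrap.
#'
#' @param values numeric marker values (higher = more case-like).
#' @param labels logical or 0/1 case indicator.
#' @param boot number of bootstrap resamples for the AUC CI (default 2000;
#'   0 skips the CI).
#' @param conf confidence level (default 0.95).
#' @param seed integer seed for the bootstrap.
#' @return an object of class `roc_result`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `auc_ci`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(values, labels, boot = 2000L, conf = 0.95, seed = 1L) {
  labels <- as.logical(labels)
  ok <- is.finite(values) & !is.na(labels)
  values <- values[ok]; labels <- labels[ok]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be non-empty", call. = FALSE)

  thr <- c(-Inf, sort(unique(values)), Inf)
  sens <- vapply(thr, function(t) mean(values[labels] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(values[!labels] < t), numeric(1))

  auc_of <- function(v, l) {
    r <- rank(v)
    (sum(r[l]) - sum(l) * (sum(l) + 1) / 2) / (sum(l) * sum(!l))
  }
  auc <- auc_of(values, labels)

  ci <- c(NA_real_, NA_real_)
  if (boot > 0) {
    set.seed(substream_seed(seed, 101L))
    pos <- values[labels]; neg <- values[!labels]
    stat <- vapply(seq_len(boot), function(b) {
      auc_of(c(sample(pos, n_pos, TRUE), sample(neg, n_neg, TRUE)),
             rep(c(TRUE, FALSE), c(n_pos, n_neg)))
    }, numeric(1))
    alpha <- (1 - conf) / 2
    ci <- unname(stats::quantile(stat, c(alpha, 1 - alpha), type = 7))
  }
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc, auc_ci = ci, n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f (%.3f-%.3f), %d pos / %d neg\n",
              x$auc, x$auc_ci[1], x$auc_ci[2], x$n_pos, x$n_neg))
  invisible(x)
}

#' Optimal ROC cutoff
#'
#' Default strategy maximizes Youden's J (sensitivity + specificity - 1) over
#' the observed thresholds; ties are broken toward the higher specificity and
#' then the lower cutoff value. The alternative strategy picks the threshold
#' closest to the (0, 1) corner of ROC space.
#'
#' @param roc a [roc_result][roc_curve()].
#' @param strategy `"youden"` (default) or `"closest01"`.
#' @return list with `cutoff`, `sensitivity`, `specificity`, `j`.
#' @export
youden_cutoff <- function(roc, strategy = c("youden", "closest01")) {
  strategy <- match.arg(strategy)
  fin <- is.finite(roc$thresholds)
  thr <- roc$thresholds[fin]
  sens <- roc$sensitivity[fin]
  spec <- roc$specificity[fin]
  score <- switch(strategy,
                  youden = sens + spec - 1,
                  closest01 = -sqrt((1 - sens)^2 + (1 - spec)^2))
  best <- max(score)
  cand <- which(score >= best - 1e-12)
  cand <- cand[order(-spec[cand], thr[cand])]
  i <- cand[1]
  list(cutoff = thr[i], sensitivity = sens[i], specificity = spec[i],
       j = sens[i] + spec[i] - 1)
}

#' Convert a continuous marker into an ordinal three-level variable
#'
#' Levels: `low` if `value < low_cut`, `mid` if `low_cut <= value < high_cut`,
#' `high` if `value >= high_cut` — a value sitting exactly on a boundary goes
#' to the upper level. Returned both as an ordered factor / integer code
#' (0/1/2) and as the two dummy indicators used in modelling.
#'
#' @param values numeric marker values (e.g. serum IgM in g/L).
#' @param low_cut,high_cut boundaries with `low_cut < high_cut`.
#' @return data.frame with `value`, `level` (ordered factor), `code`,
#'   `mid`, `high`.
#' @export
ordinalize <- function(values, low_cut, high_cut) {
  if (!(low_cut < high_cut))
    stop("low_cut must be strictly below high_cut", call. = FALSE)
  code <- ifelse(values >= high_cut, 2L, ifelse(values >= low_cut, 1L, 0L))
  level <- factor(c("low", "mid", "high")[code + 1L],
                  levels = c("low", "mid", "high"), ordered = TRUE)
  data.frame(value = values, level = level, code = code,
             mid = as.integer(code == 1L), high = as.integer(code == 2L))
}
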