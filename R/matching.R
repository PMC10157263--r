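# Propensity-score matching: logistic propensity model over clinical
# covariates (dates entering as days since the earliest), greedy 1:1
# nearest-neighbour matching without replacement on the propensity logit,
# and standardized-mean-difference balance diagnostics.

# expand covariates to a numeric design; dates -> days since earliest,
# factors/characters -> dummy columns (first level reference), logicals -> 0/1
.covariate_design <- function(cohort, covariate_names) {
  cols <- list()
  for (nm in covariate_names) {
    v <- cohort[[nm]]
    if (is.null(v)) stop("covariate not found: ", nm, call. = FALSE)
    if (inherits(v, "Date")) {
      cols[[nm]] <- as.numeric(v - min(v))
    } else if (is.logical(v)) {
      cols[[nm]] <- as.numeric(v)
    } else if (is.factor(v) || is.character(v)) {
      f <- factor(v)
      for (lv in levels(f)[-1])
        cols[[paste0(nm, ".", lv)]] <- as.numeric(f == lv)
    } else {
      cols[[nm]] <- as.numeric(v)
    }
  }
  do.call(cbind, cols)
}

#' Standardized mean difference of a covariate between two groups
#'
#' Continuous: difference in means over the pooled standard deviation.
#' Binary (0/1): difference in proportions over
#' `sqrt((p1(1-p1) + p0(1-p0)) / 2)`.
#'
#' @param x numeric covariate.
#' @param g logical group indicator.
#' @return signed SMD (0 when both groups are constant and equal).
#' @export
smd <- function(x, g) {
  x1 <- x[g]; x0 <- x[!g]
  m1 <- mean(x1); m0 <- mean(x0)
  if (all(x %in% c(0, 1))) {
    s <- sqrt((m1 * (1 - m1) + m0 * (1 - m0)) / 2)
  } else {
    s <- sqrt((stats::var(x1) + stats::var(x0)) / 2)
  }
  if (!is.finite(s) || s == 0) return(if (m1 == m0) 0 else Inf)
  (m1 - m0) / s
}

#' Propensity-score matching with balance diagnostics
#'
#' Estimates the propensity of case status by logistic regression on the
#' covariates, then matches each case 1:1 without replacement to the nearest
#' available control on the propensity logit, processing cases in descending
#' propensity order. An optional caliper (in SD units of the logit) discards
#' pairs beyond the allowed distance. SMDs for every expanded covariate column
#' are reported before and after matching.
#'
#' @param cohort data.frame with a `subject_id` column.
#' @param covariate_names covariate columns for the propensity model.
#' @param case_indicator logical vector (or name of a logical column) marking
#'   cases.
#' @param caliper optional caliper width in SDs of the propensity logit
#'   (default `Inf`, plain 1:1 matching).
#' @return an object of class `match_result`: `pairs` (case_id, control_id,
#'   distance), `propensity` (named per-subject), `smd_before`, `smd_after`,
#'   `unmatched_cases`.
#' @export
propensity_match <- function(cohort, covariate_names, case_indicator,
                             caliper = Inf) {
  if (is.character(case_indicator) && length(case_indicator) == 1L)
    case_indicator <- as.logical(cohort[[case_indicator]])
  g <- as.logical(case_indicator)
  stopifnot(length(g) == nrow(cohort))
  if (!any(g) || all(g)) stop("both classes must be non-empty", call. = FALSE)

  Xc <- .covariate_design(cohort, covariate_names)
  fit <- fit_logistic(cbind(`(Intercept)` = 1, Xc), g)
  ps <- fit$fitted
  names(ps) <- cohort$subject_id
  lp <- stats::qlogis(pmin(pmax(ps, 1e-12), 1 - 1e-12))
  cal_dist <- caliper * stats::sd(lp)

  case_idx <- which(g)[order(-ps[g])]
  avail <- which(!g)
  pairs <- list()
  unmatched <- character(0)
  for (i in case_idx) {
    if (!length(avail)) { unmatched <- c(unmatched, cohort$subject_id[i]); next }
    d <- abs(lp[avail] - lp[i])
    j <- which.min(d)
    if (d[j] > cal_dist) { unmatched <- c(unmatched, cohort$subject_id[i]); next }
    pairs[[length(pairs) + 1L]] <- data.frame(
      case_id = cohort$subject_id[i],
      control_id = cohort$subject_id[avail[j]],
      distance = unname(d[j]), stringsAsFactors = FALSE)
    avail <- avail[-j]
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(case_id = character(0), control_id = character(0),
               distance = numeric(0))

  smd_all <- function(rows) {
    vapply(seq_len(ncol(Xc)), function(k) smd(Xc[rows, k], g[rows]), numeric(1))
  }
  matched_rows <- match(c(pairs$case_id, pairs$control_id), cohort$subject_id)
  structure(list(pairs = pairs,
                 propensity = ps,
                 smd_before = stats::setNames(smd_all(seq_len(nrow(cohort))),
                                              colnames(Xc)),
                 smd_after = stats::setNames(
                   if (length(matched_rows)) smd_all(matched_rows)
                   else rep(NA_real_, ncol(Xc)), colnames(Xc)),
                 unmatched_cases = unmatched),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d pairs; max |SMD| before %.3f -> after %.3f\n",
              nrow(x$pairs), max(abs(x$smd_before)),
              suppressWarnings(max(abs(x$smd_after)))))
  invisible(x)
}

#' Subset a cohort to the matched subjects
#' @param cohort data.frame with `subject_id`.
#' @param match a [propensity_match()] result.
#' @return the matched rows of `cohort`.
#' @export
matched_cohort <- function(cohort, match) {
  cohort[cohort$subject_id %in% c(match$pairs$case_id, match$pairs$control_id), ,
         drop = FALSE]
}
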