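# Absolute kappa/lambda monoclonality score. Monoclonal B-cell populations
# express a single light chain, skewing the kappa/lambda output ratio in
# either direction; the absolute log2 ratio quantifies the skew symmetrically
# so kappa-restricted and lambda-restricted clones score alike.

#' Absolute kappa/lambda monoclonality score
#'
#' `|log2((kappa + eps) / (lambda + eps))|` by default. The score is zero for
#' balanced chains, symmetric under swapping kappa and lambda, and strictly
#' increasing in the log-scale imbalance. Alternative monotone variants
#' (absolute log10 ratio, max/min ratio) are provided because every
#' rank-based downstream comparison is invariant to the choice.
#'
#' @param kappa,lambda non-negative abundances (vectors recycle).
#' @param pseudocount positive offset guarding against zero abundances.
#' @param variant score definition; default `"abs_log2"`.
#' @return non-negative numeric score(s).
#' @export
kappa_lambda_score <- function(kappa, lambda, pseudocount = 1e-3,
                               variant = c("abs_log2", "abs_log10", "max_min")) {
  variant <- match.arg(variant)
  if (any(kappa < 0, na.rm = TRUE) || any(lambda < 0, na.rm = TRUE))
    stop("abundances must be non-negative", call. = FALSE)
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stop("pseudocount must be positive", call. = FALSE)
  # computed as |log(k+eps) - log(l+eps)| so the swap symmetry is exact in
  # floating point, not just analytically
  switch(variant,
         abs_log2 = abs(log2(kappa + pseudocount) - log2(lambda + pseudocount)),
         abs_log10 = abs(log10(kappa + pseudocount) - log10(lambda + pseudocount)),
         max_min = (pmax(kappa, lambda) + pseudocount) /
           (pmin(kappa, lambda) + pseudocount))
}

#' Rank-sum comparison of scores between groups
#'
#' Runs a two-sided Wilcoxon rank-sum test for each requested contrast and
#' reports the U statistic, p-value and group medians. Uses the exact null
#' distribution when both groups are small and tie-free (the
#' [stats::wilcox.test()] convention); degenerate contrasts where all values
#' are tied return `p = 1`.
#'
#' @param scores numeric vector.
#' @param groups group label per score.
#' @param contrasts list of 2-vectors of group labels; default: first level vs
#'   each other level.
#' @return data.frame with one row per contrast.
#' @export
compare_scores <- function(scores, groups, contrasts = NULL) {
  groups <- as.character(groups)
  lv <- unique(groups)
  if (is.null(contrasts))
    contrasts <- lapply(lv[-1], function(g) c(lv[1], g))
  rows <- lapply(contrasts, function(ct) {
    x <- scores[groups == ct[1]]
    y <- scores[groups == ct[2]]
    if (!length(x) || !length(y))
      stop("empty group in contrast ", paste(ct, collapse = " vs "), call. = FALSE)
    if (length(unique(c(x, y))) == 1L) {
      u <- length(x) * length(y) / 2
      p <- 1
    } else {
      wt <- suppressWarnings(stats::wilcox.test(x, y))
      u <- unname(wt$statistic)
      p <- wt$p.value
    }
    data.frame(group1 = ct[1], group2 = ct[2],
               n1 = length(x), n2 = length(y),
               median1 = stats::median(x), median2 = stats::median(y),
               statistic = u, p_value = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-group cross-layer correlation of clonality scores
#'
#' Spearman correlation of the transcriptome-layer score against the
#' proteome-layer score, per diagnosis group, over subjects scored in both
#' layers. Groups with fewer than `min_n` doubly-scored subjects are flagged
#' with `rho = NA`.
#'
#' @param transcript_scores,protein_scores named numeric vectors keyed by
#'   subject id.
#' @param group_labels named group label per subject.
#' @param min_n minimum subjects per group (default 5).
#' @return data.frame with `group`, `rho`, `p_value`, `n`, `flagged`.
#' @export
score_cross_layer_correlation <- function(transcript_scores, protein_scores,
                                          group_labels, min_n = 5L) {
  shared <- intersect(names(transcript_scores), names(protein_scores))
  per_group_correlation(transcript_scores[shared], protein_scores[shared],
                        group_labels[shared], min_n = min_n)
}

#' Per-group correlation of clonality score with a serum marker
#'
#' @param scores named serum-layer clonality scores keyed by subject id.
#' @param marker_abundance named serum marker abundances.
#' @param group_labels named group label per subject.
#' @param min_n minimum subjects per group.
#' @return data.frame with `group`, `rho`, `p_value`, `n`, `flagged`.
#' @export
score_marker_correlation <- function(scores, marker_abundance, group_labels,
                                     min_n = 5L) {
  shared <- intersect(names(scores), names(marker_abundance))
  per_group_correlation(scores[shared], marker_abundance[shared],
                        group_labels[shared], min_n = min_n)
}

per_group_correlation <- function(x, y, groups, min_n = 5L) {
  lv <- unique(as.character(groups))
  rows <- lapply(lv, function(g) {
    sel <- which(groups == g & is.finite(x) & is.finite(y))
    if (length(sel) < min_n)
      return(data.frame(group = g, rho = NA_real_, p_value = NA_real_,
                        n = length(sel), flagged = TRUE,
                        stringsAsFactors = FALSE))
    st <- spearman_test(x[sel], y[sel], min_n = min_n)
    data.frame(group = g, rho = st$rho, p_value = st$p_value,
               n = st$n, flagged = !is.finite(st$rho),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
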