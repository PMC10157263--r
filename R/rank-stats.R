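# Vectorized rank statistics used across the differential-expression and
# correlation stages. These reproduce, feature-by-feature, what
# stats::wilcox.test(exact = FALSE, correct = TRUE) and
# stats::cor.test(method = "spearman", exact = FALSE) compute, but operate on
# whole matrices at once so a 1000-feature layer is tested in milliseconds.

#' Row-wise two-sided Wilcoxon rank-sum test
#'
#' Applies the two-sided Wilcoxon rank-sum (Mann-Whitney) test to every row of
#' a matrix, comparing the `case_idx` columns against the `control_idx`
#' columns. Uses the normal approximation with tie correction and continuity
#' correction, matching [stats::wilcox.test()] with `exact = FALSE`. Rows with
#' zero variance across both groups (all values tied) get `p = 1`.
#'
#' @param mat numeric matrix, features in rows.
#' @param case_idx,control_idx disjoint column indices.
#' @return data.frame with columns `statistic` (Mann-Whitney U of the case
#'   group) and `p_value`.
#' @export
row_rank_sum <- function(mat, case_idx, control_idx) {
  mat <- as.matrix(mat)
  n1 <- length(case_idx)
  n2 <- length(control_idx)
  stopifnot(n1 >= 1, n2 >= 1, !any(case_idx %in% control_idx))
  n <- n1 + n2
  sub <- mat[, c(case_idx, control_idx), drop = FALSE]
  rk <- t(apply(sub, 1L, rank))
  if (nrow(sub) == 1L) rk <- matrix(rk, nrow = 1L)
  r1 <- rowSums(rk[, seq_len(n1), drop = FALSE])
  u <- r1 - n1 * (n1 + 1) / 2
  # tie correction: sum over tie groups of (t^3 - t), per row
  tie_term <- apply(sub, 1L, function(x) {
    t <- table(x)
    sum(t^3 - t)
  })
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term / (n * (n - 1)))
  z <- u - n1 * n2 / 2
  p <- ifelse(sigma2 <= 0, 1,
              2 * stats::pnorm(-(abs(z) - 0.5) / sqrt(pmax(sigma2, 0))))
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  data.frame(statistic = u, p_value = p)
}

#' Row-wise Spearman correlation between two matrices
#'
#' Computes, for each row `i`, the Spearman rank correlation between
#' `x[i, ]` and `y[i, ]` across columns (subjects), with average-rank tie
#' handling, and a two-sided p-value from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom —
#' the same approximation [stats::cor.test()] uses for Spearman when an exact
#' p is unavailable. Rows with fewer than `min_n` complete (non-missing in
#' both matrices) columns are returned with `rho = NA` and `flagged = TRUE`.
#'
#' @param x,y numeric matrices of identical dimension.
#' @param min_n minimum complete observations per row (default 5).
#' @return data.frame with `rho`, `p_value`, `n_subjects`, `flagged`.
#' @export
row_spearman <- function(x, y, min_n = 5L) {
  stopifnot(all(dim(x) == dim(y)))
  m <- nrow(x)
  rho <- rep(NA_real_, m)
  p <- rep(NA_real_, m)
  nn <- integer(m)
  for (i in seq_len(m)) {
    ok <- is.finite(x[i, ]) & is.finite(y[i, ])
    nn[i] <- sum(ok)
    if (nn[i] < min_n) next
    rx <- rank(x[i, ok])
    ry <- rank(y[i, ok])
    sx <- stats::sd(rx)
    sy <- stats::sd(ry)
    if (sx == 0 || sy == 0) { rho[i] <- NA_real_; next }
    r <- stats::cor(rx, ry)
    rho[i] <- r
    if (abs(r) >= 1) {
      p[i] <- 0
    } else {
      tval <- r * sqrt((nn[i] - 2) / (1 - r^2))
      p[i] <- 2 * stats::pt(-abs(tval), df = nn[i] - 2)
    }
  }
  data.frame(rho = rho, p_value = pmin(pmax(p, .Machine$double.xmin), 1),
             n_subjects = nn, flagged = !is.finite(rho))
}

#' Exact two-sided rank-sum p-value by permutation enumeration
#'
#' Enumerates every assignment of the pooled observations to the two groups
#' and doubles the smaller tail of the Mann-Whitney U distribution. Valid
#' under ties (which the large-sample exact distribution is not), but
#' combinatorial — intended for small groups only.
#'
#' @param x,y numeric group samples; `choose(length(x) + length(y), length(x))`
#'   must stay manageable (enforced at 1e6).
#' @return two-sided p-value.
#' @export
exact_rank_sum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (choose(n1 + n2, n1) > 1e6)
    stop("groups too large for exact enumeration", call. = FALSE)
  v <- c(x, y)
  if (length(unique(v)) == 1L) return(1)
  r <- rank(v)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u_all <- utils::combn(n1 + n2, n1,
                        function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(u_all <= u_obs + 1e-9), mean(u_all >= u_obs - 1e-9)))
}

#' Spearman correlation with t-approximation p-value
#'
#' Scalar convenience wrapper around [row_spearman()] for two vectors.
#'
#' @param x,y numeric vectors.
#' @param min_n minimum complete pairs.
#' @return list with `rho`, `p_value`, `n`.
#' @export
spearman_test <- function(x, y, min_n = 5L) {
  res <- row_spearman(matrix(x, nrow = 1L), matrix(y, nrow = 1L), min_n = min_n)
  list(rho = res$rho, p_value = res$p_value, n = res$n_subjects)
}
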