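# Brute-force oracles, independent of the package implementation paths they
# check: exhaustive permutation enumeration for the rank-sum and signed-rank
# tests, explicit pair counting for the AUC, and rank-construction Pearson
# for Spearman.

# two-sided rank-sum p by enumerating all group assignments
perm_rank_sum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  all_v <- c(x, y)
  combs <- utils::combn(n1 + n2, n1)
  r <- rank(all_v)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u_all <- apply(combs, 2L, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p_low <- mean(u_all <= u_obs + 1e-9)
  p_high <- mean(u_all >= u_obs - 1e-9)
  min(1, 2 * min(p_low, p_high))
}

# two-sided one-sample signed-rank p by enumerating all sign assignments
perm_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  p_low <- mean(v_all <= v_obs + 1e-9)
  p_high <- mean(v_all >= v_obs - 1e-9)
  min(1, 2 * min(p_low, p_high))
}

# AUC as explicit pair counting: wins + half ties over all pos x neg pairs
pair_counting_auc <- function(values, labels) {
  pos <- values[as.logical(labels)]
  neg <- values[!as.logical(labels)]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# tiny deterministic cohort for matching / modelling tests
toy_cohort <- function(n = 40, seed = 1) {
  cfg <- cohort_sim_config(n_per_class = c(n / 4, n / 4, n / 4, n / 4),
                           seed = seed)
  generate_cohort(cfg)
}
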