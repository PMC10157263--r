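# Differential expression, cross-layer Spearman correlation, and the
# tumour-derived intersection criterion.

make_expr <- function(values, layer = "proteome", prefix = "F") {
  expression_matrix(values, sprintf("%s%03d", prefix, seq_len(nrow(values))),
                    sprintf("S%03d", seq_len(ncol(values))), layer)
}

test_that("expression_matrix rejects duplicates and negative values", {
  m <- matrix(1:4, 2)
  expect_error(expression_matrix(m, c("a", "a"), c("s1", "s2")), "duplicate feature")
  expect_error(expression_matrix(m, c("a", "b"), c("s1", "s1")), "duplicate subject")
  expect_error(expression_matrix(-m, c("a", "b"), c("s1", "s2")), "non-negative")
})

test_that("exact doubling yields log2 fold change of 1 for every feature", {
  set.seed(1)
  ctrl <- matrix(runif(20 * 4, 1, 10), 20)
  vals <- cbind(2 * ctrl, ctrl)
  em <- make_expr(vals)
  de <- differential_expression(em, sprintf("S%03d", 1:4), sprintf("S%03d", 5:8),
                                pseudocount = 1e-12, normalize = FALSE)
  expect_equal(de$log2fc, rep(1, 20), tolerance = 1e-9)
})

test_that("row_rank_sum matches wilcox.test's normal approximation, ties included", {
  set.seed(7)
  m <- matrix(sample(1:6, 30 * 15, replace = TRUE) + 0, 30)  # heavy ties
  m <- rbind(m, matrix(rnorm(10 * 15), 10))                  # continuous
  res <- row_rank_sum(m, 1:7, 8:15)
  for (i in seq_len(nrow(m))) {
    wt <- suppressWarnings(wilcox.test(m[i, 1:7], m[i, 8:15],
                                       exact = FALSE, correct = TRUE))
    expect_equal(res$statistic[i], unname(wt$statistic))
    expect_equal(res$p_value[i], wt$p.value, tolerance = 1e-12)
  }
  # all-tied row gets p = 1
  flat <- row_rank_sum(matrix(5, 1, 15), 1:7, 8:15)
  expect_equal(flat$p_value, 1)
})

test_that("exact rank-sum p-values match permutation enumeration at n <= 6", {
  set.seed(11)
  for (rep in 1:10) {
    x <- round(rlnorm(5), 1); y <- round(rlnorm(6), 1)  # ties likely
    em <- make_expr(matrix(c(x, y), 1))
    de <- differential_expression(em, sprintf("S%03d", 1:5),
                                  sprintf("S%03d", 6:11),
                                  normalize = FALSE, exact = TRUE,
                                  pseudocount = 1)
    expect_equal(de$p_value, perm_rank_sum_p(x, y), tolerance = 1e-12)
    # on tie-free data the enumeration reproduces the classical exact test
    if (!anyDuplicated(c(x, y)))
      expect_equal(de$p_value, wilcox.test(x, y, exact = TRUE)$p.value,
                   tolerance = 1e-12)
  }
})

test_that("null data gives nominal false-positive rate and valid BH q-values", {
  set.seed(3)
  em <- make_expr(matrix(rlnorm(1000 * 20), 1000))
  de <- differential_expression(em, sprintf("S%03d", 1:10),
                                sprintf("S%03d", 11:20))
  expect_lt(abs(mean(de$p_value < 0.05) - 0.05), 0.025)
  expect_true(all(de$q_value >= de$p_value - 1e-12))
  o <- order(de$p_value)
  expect_true(all(diff(de$q_value[o]) >= -1e-12))
  expect_equal(de$q_value, p.adjust(de$p_value, "BH"))
})

test_that("differential_expression validates its inputs", {
  em <- make_expr(matrix(1:8 + 0, 2))
  expect_error(differential_expression(em, c("S001", "S999"), c("S003", "S004")),
               "unknown subject")
  expect_error(differential_expression(em, c("S001", "S002"), c("S002", "S003")),
               "disjoint")
  expect_error(differential_expression(em, "S001", c("S002", "S003")),
               "at least 2")
})

test_that("Spearman correlation is exactly 1 under a monotone transform and matches cor.test", {
  set.seed(5)
  p <- matrix(rlnorm(10 * 12), 10)
  t_ <- exp(p) + 7            # strictly increasing transform of each row
  po <- paired_omics(make_expr(p, "proteome", "P"),
                     make_expr(t_, "transcriptome", "T"),
                     data.frame(protein_id = sprintf("P%03d", 1:10),
                                transcript_id = sprintf("T%03d", 1:10),
                                gene_symbol = sprintf("G%03d", 1:10)))
  corrs <- pair_correlation(po)
  expect_equal(corrs$rho, rep(1, 10))
  expect_equal(corrs$p_value, rep(.Machine$double.xmin, 10))

  # ties: agree with cor.test's t approximation
  set.seed(6)
  a <- sample(1:4, 12, replace = TRUE) + 0
  b <- sample(1:4, 12, replace = TRUE) + 0
  st <- spearman_test(a, b)
  ct <- suppressWarnings(cor.test(a, b, method = "spearman", exact = FALSE))
  expect_equal(st$rho, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(st$p_value, ct$p.value, tolerance = 1e-12)
})

test_that("Spearman rho equals Pearson on constructed ranks over all permutations at n = 5", {
  perms <- as.matrix(expand.grid(rep(list(1:5), 5)))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 5), ]
  x <- c(2.3, -1.1, 0.4, 5.2, 3.3)
  for (i in seq_len(nrow(perms))) {
    y <- perms[i, ]
    st <- spearman_test(x, y)
    expect_equal(st$rho, cor(rank(x), rank(y)), tolerance = 1e-12)
  }
})

test_that("pairs below min_n complete observations are flagged undefined", {
  p <- matrix(c(1, 2, 3, NA, NA, NA, NA, NA,
                1, 2, 3, 4, 5, 6, 7, 8), 2, byrow = TRUE)
  t_ <- matrix(rep(1:8, 2), 2, byrow = TRUE) + 0
  res <- row_spearman(p, t_, min_n = 5)
  expect_true(res$flagged[1])
  expect_false(res$flagged[2])
  expect_true(is.na(res$rho[1]))
})

test_that("selection respects thresholds, monotonicity and concordance", {
  po <- generate_paired_omics(omics_sim_config(n_pairs = 300, seed = 8))
  de_p <- differential_expression(po$proteome, po$case_ids$proteome,
                                  po$control_ids$proteome)
  de_t <- differential_expression(po$transcriptome, po$case_ids$transcriptome,
                                  po$control_ids$transcriptome)
  corrs <- pair_correlation(po)
  sel <- select_tumour_derived(de_p, de_t, corrs, pair_map = po$pair_map)
  expect_true(po$planted %in% sel$gene_symbol[sel$selected])

  # thresholds at +infinity: empty set
  hi <- selection_thresholds(prot_log2fc_min = 1e6, trans_log2fc_min = 1e6)
  sel_hi <- select_tumour_derived(de_p, de_t, corrs, hi, pair_map = po$pair_map)
  expect_equal(sum(sel_hi$selected), 0)

  # relaxing every threshold never removes a candidate
  lax <- selection_thresholds(prot_log2fc_min = 0.01, trans_log2fc_min = 0.01,
                              alpha_de = 0.2, alpha_corr = 0.2,
                              require_concordant_direction = FALSE)
  sel_lax <- select_tumour_derived(de_p, de_t, corrs, lax, pair_map = po$pair_map)
  expect_true(all(sel$gene_symbol[sel$selected] %in%
                    sel_lax$gene_symbol[sel_lax$selected]))

  # gene missing from a DE table: warned and excluded
  de_p2 <- de_p[-match(sub("G", "P", po$planted), de_p$feature_id), ]
  expect_warning(
    sel2 <- select_tumour_derived(de_p2, de_t, corrs, pair_map = po$pair_map),
    "missing")
  expect_false(po$planted %in% sel2$gene_symbol[sel2$selected])
})

test_that("all-null data yields at most a handful of false candidates", {
  counts <- vapply(1:10, function(s) {
    po <- generate_paired_omics(omics_sim_config(
      n_pairs = 500, planted_log2fc_prot = 0, planted_log2fc_trans = 0,
      cross_omics_rho = 0, seed = s))
    de_p <- differential_expression(po$proteome, po$case_ids$proteome,
                                    po$control_ids$proteome)
    de_t <- differential_expression(po$transcriptome, po$case_ids$transcriptome,
                                    po$control_ids$transcriptome)
    sel <- select_tumour_derived(de_p, de_t, pair_correlation(po),
                                 pair_map = po$pair_map)
    sum(sel$selected)
  }, numeric(1))
  expect_lte(stats::median(counts), 2)
})

test_that("isotype panel summary is a pure restriction of the full tables", {
  po <- generate_paired_omics(omics_sim_config(n_pairs = 50, seed = 4))
  de_p <- differential_expression(po$proteome, po$case_ids$proteome,
                                  po$control_ids$proteome)
  de_t <- differential_expression(po$transcriptome, po$case_ids$transcriptome,
                                  po$control_ids$transcriptome)
  de_p$gene_symbol <- po$pair_map$gene_symbol
  de_t$gene_symbol <- po$pair_map$gene_symbol
  corrs <- pair_correlation(po)

  one <- isotype_panel_summary(de_p, de_t, corrs, "G0007")
  expect_equal(nrow(one), 1)
  expect_equal(one$rho, corrs$rho[corrs$gene_symbol == "G0007"])
  expect_equal(one$log2fc_prot, de_p$log2fc[de_p$gene_symbol == "G0007"])

  empty <- isotype_panel_summary(de_p, de_t, corrs, character(0))
  expect_equal(nrow(empty), 0)

  part <- isotype_panel_summary(de_p, de_t, corrs, c("G0007", "IGHD"))
  expect_equal(attr(part, "missing"), "IGHD")
  expect_equal(nrow(part), 1)
})
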