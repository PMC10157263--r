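# Tumour-derived serum biomarker discovery: per-layer differential
# expression, across-subject protein-mRNA Spearman correlation over the
# subjects measured in both layers, and the intersection criterion that calls
# a gene tumour-derived when it is concordantly dysregulated in both layers
# AND significantly positively correlated across them.

#' Construct a single-layer expression matrix
#'
#' @param values non-negative numeric matrix, features in rows, subjects in
#'   columns.
#' @param feature_ids,subject_ids unique identifiers for rows / columns.
#' @param layer `"proteome"` or `"transcriptome"`.
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, feature_ids, subject_ids,
                              layer = c("proteome", "transcriptome")) {
  layer <- match.arg(layer)
  values <- as.matrix(values)
  if (length(feature_ids) != nrow(values) || length(subject_ids) != ncol(values))
    stop("id lengths do not match matrix dimensions", call. = FALSE)
  if (anyDuplicated(feature_ids))
    stop("duplicate feature id: ",
         feature_ids[duplicated(feature_ids)][1], call. = FALSE)
  if (anyDuplicated(subject_ids))
    stop("duplicate subject id: ",
         subject_ids[duplicated(subject_ids)][1], call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0))
    stop("abundances must be finite and non-negative", call. = FALSE)
  dimnames(values) <- list(feature_ids, subject_ids)
  structure(list(layer = layer, values = values), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %s: %d features x %d subjects\n",
              x$layer, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Pair two omics layers through an identifier map
#'
#' @param proteome,transcriptome [expression_matrix()] objects.
#' @param pair_map data.frame with columns `protein_id`, `transcript_id`,
#'   `gene_symbol`; every entry must resolve in its layer.
#' @return an object of class `paired_omics` with the shared subject ids.
#' @export
paired_omics <- function(proteome, transcriptome, pair_map) {
  stopifnot(inherits(proteome, "expression_matrix"),
            inherits(transcriptome, "expression_matrix"))
  need <- c("protein_id", "transcript_id", "gene_symbol")
  if (!all(need %in% names(pair_map)))
    stop("pair_map needs columns protein_id, transcript_id, gene_symbol",
         call. = FALSE)
  missing_p <- setdiff(pair_map$protein_id, rownames(proteome$values))
  missing_t <- setdiff(pair_map$transcript_id, rownames(transcriptome$values))
  if (length(missing_p))
    stop("pair_map protein ids not in proteome: ",
         paste(utils::head(missing_p, 3), collapse = ", "), call. = FALSE)
  if (length(missing_t))
    stop("pair_map transcript ids not in transcriptome: ",
         paste(utils::head(missing_t, 3), collapse = ", "), call. = FALSE)
  shared <- intersect(colnames(proteome$values), colnames(transcriptome$values))
  structure(list(proteome = proteome, transcriptome = transcriptome,
                 pair_map = pair_map, shared_subjects = shared),
            class = "paired_omics")
}

#' @export
print.paired_omics <- function(x, ...) {
  cat(sprintf("<paired_omics> %d pairs; %d proteome + %d transcriptome subjects (%d shared)\n",
              nrow(x$pair_map), ncol(x$proteome$values),
              ncol(x$transcriptome$values), length(x$shared_subjects)))
  invisible(x)
}

#' Default pseudocount: half the smallest nonzero value of a layer
#' @param values non-negative matrix.
#' @return a positive scalar.
#' @export
default_pseudocount <- function(values) {
  nz <- values[values > 0]
  if (!length(nz)) return(.Machine$double.eps)
  min(nz) / 2
}

#' Per-feature differential expression between cases and controls
#'
#' Log2 fold change is the difference of group means of `log2(x + pseudocount)`
#' computed on (optionally library-size normalized) abundances; the p-value is
#' a two-sided Wilcoxon rank-sum test per feature and q-values are
#' Benjamini-Hochberg across all features of the layer. Features tied across
#' both groups receive `p = 1`.
#'
#' @param matrix an [expression_matrix()].
#' @param case_ids,control_ids disjoint subject id sets, each of size >= 2.
#' @param pseudocount positive offset added before log2; default half the
#'   smallest nonzero abundance in the layer.
#' @param normalize scale columns to a common total abundance before testing
#'   (default TRUE).
#' @param exact use the exact rank-sum distribution per feature (small-sample
#'   oracle mode); default FALSE uses the tie-corrected normal approximation.
#' @return data.frame with `feature_id`, `log2fc`, `p_value`, `q_value`.
#' @export
differential_expression <- function(matrix, case_ids, control_ids,
                                    pseudocount = NULL, normalize = TRUE,
                                    exact = FALSE) {
  stopifnot(inherits(matrix, "expression_matrix"))
  vals <- matrix$values
  unknown <- setdiff(c(case_ids, control_ids), colnames(vals))
  if (length(unknown))
    stop("unknown subject id: ", paste(unknown, collapse = ", "), call. = FALSE)
  if (length(intersect(case_ids, control_ids)))
    stop("case and control ids must be disjoint", call. = FALSE)
  if (length(case_ids) < 2 || length(control_ids) < 2)
    stop("need at least 2 subjects per group", call. = FALSE)

  if (normalize) {
    cs <- colSums(vals)
    vals <- sweep(vals, 2L, cs / mean(cs), "/")
  }
  pc <- pseudocount %||% default_pseudocount(vals)
  if (pc <= 0) stop("pseudocount must be positive", call. = FALSE)

  lv <- log2(vals + pc)
  ci <- match(case_ids, colnames(vals))
  ki <- match(control_ids, colnames(vals))
  log2fc <- rowMeans(lv[, ci, drop = FALSE]) - rowMeans(lv[, ki, drop = FALSE])

  if (exact) {
    p <- vapply(seq_len(nrow(vals)), function(i)
      exact_rank_sum_p(vals[i, ci], vals[i, ki]), numeric(1))
  } else {
    p <- row_rank_sum(vals, ci, ki)$p_value
  }
  data.frame(feature_id = rownames(vals), log2fc = log2fc, p_value = p,
             q_value = stats::p.adjust(p, method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Across-subject Spearman correlation for every protein-mRNA pair
#'
#' For each mapped pair, the Spearman rank correlation of protein abundance
#' vs transcript abundance across the subjects measured in both layers, with
#' average-rank ties and a two-sided p from the t approximation. Pairs with
#' fewer than `min_n` complete observations are emitted with `rho = NA` and
#' `flagged = TRUE`.
#'
#' @param paired a [paired_omics()] object.
#' @param min_n minimum complete subject pairs (default 5).
#' @return data.frame with `gene_symbol`, `rho`, `p_value`, `n_subjects`,
#'   `flagged`.
#' @export
pair_correlation <- function(paired, min_n = 5L) {
  stopifnot(inherits(paired, "paired_omics"))
  sh <- paired$shared_subjects
  if (!length(sh)) stop("no shared subjects between layers", call. = FALSE)
  px <- paired$proteome$values[paired$pair_map$protein_id, sh, drop = FALSE]
  tx <- paired$transcriptome$values[paired$pair_map$transcript_id, sh, drop = FALSE]
  res <- row_spearman(px, tx, min_n = min_n)
  cbind(data.frame(gene_symbol = paired$pair_map$gene_symbol,
                   stringsAsFactors = FALSE), res)
}

#' Thresholds of the tumour-derived selection criterion
#'
#' Defaults follow the dual fold-change convention of the paired-omics design:
#' proteomic |log2 FC| at log2(1.2), transcriptomic |log2 FC| at log2(1.5),
#' q < 0.05 in both layers, unadjusted correlation p < 0.05 with rho > 0, and
#' concordant fold-change direction.
#'
#' @param prot_log2fc_min,trans_log2fc_min minimum absolute log2 fold change.
#' @param alpha_de significance level on the per-layer q-values.
#' @param alpha_corr significance level on the correlation p-value.
#' @param adjust_corr apply Benjamini-Hochberg to correlation p-values before
#'   thresholding (default FALSE: raw p, matching how single-pair correlations
#'   are usually reported in this design).
#' @param require_concordant_direction require the two layers' fold changes to
#'   share a sign.
#' @return an object of class `selection_thresholds`.
#' @export
selection_thresholds <- function(prot_log2fc_min = log2(1.2),
                                 trans_log2fc_min = log2(1.5),
                                 alpha_de = 0.05, alpha_corr = 0.05,
                                 adjust_corr = FALSE,
                                 require_concordant_direction = TRUE) {
  stopifnot(prot_log2fc_min > 0, trans_log2fc_min > 0,
            alpha_de > 0, alpha_de < 1, alpha_corr > 0, alpha_corr < 1)
  structure(list(prot_log2fc_min = prot_log2fc_min,
                 trans_log2fc_min = trans_log2fc_min,
                 alpha_de = alpha_de, alpha_corr = alpha_corr,
                 adjust_corr = isTRUE(adjust_corr),
                 require_concordant_direction = isTRUE(require_concordant_direction)),
            class = "selection_thresholds")
}

#' Intersect dysregulation and cross-layer correlation into candidate genes
#'
#' A gene is called tumour-derived when it is (a) positively and significantly
#' correlated between layers, (b) differentially expressed beyond the
#' fold-change and q thresholds in the proteome, (c) likewise in the
#' transcriptome, and (d) concordant in direction (when required). The
#' returned rationale table records each criterion per gene.
#'
#' @param de_prot,de_trans differential-expression tables (see
#'   [differential_expression()]) indexed by `gene_symbol` (a `gene_symbol`
#'   column, or supplied via `pair_map`).
#' @param corrs correlation table from [pair_correlation()].
#' @param thresholds a [selection_thresholds()].
#' @param pair_map optional map used to attach gene symbols to DE tables keyed
#'   by layer feature ids.
#' @return data.frame rationale with one row per gene in `corrs`, logical
#'   criterion columns, and `selected`; candidates are `x$gene_symbol[x$selected]`.
#' @export
select_tumour_derived <- function(de_prot, de_trans, corrs,
                                  thresholds = selection_thresholds(),
                                  pair_map = NULL) {
  stopifnot(inherits(thresholds, "selection_thresholds"))
  attach_symbol <- function(de, id_col) {
    if ("gene_symbol" %in% names(de)) return(de)
    if (is.null(pair_map))
      stop("DE table lacks gene_symbol and no pair_map given", call. = FALSE)
    de$gene_symbol <- pair_map$gene_symbol[match(de$feature_id, pair_map[[id_col]])]
    de
  }
  de_prot <- attach_symbol(de_prot, "protein_id")
  de_trans <- attach_symbol(de_trans, "transcript_id")

  genes <- corrs$gene_symbol
  miss_p <- setdiff(genes, de_prot$gene_symbol)
  miss_t <- setdiff(genes, de_trans$gene_symbol)
  dropped <- union(miss_p, miss_t)
  if (length(dropped))
    warning("genes missing from a DE table excluded: ",
            paste(utils::head(dropped, 5), collapse = ", "))

  ip <- match(genes, de_prot$gene_symbol)
  it <- match(genes, de_trans$gene_symbol)
  p_corr <- if (thresholds$adjust_corr)
    stats::p.adjust(corrs$p_value, "BH") else corrs$p_value

  pass_corr <- !is.na(corrs$rho) & corrs$rho > 0 &
    !is.na(p_corr) & p_corr < thresholds$alpha_corr
  pass_prot <- !is.na(ip) & abs(de_prot$log2fc[ip]) >= thresholds$prot_log2fc_min &
    de_prot$q_value[ip] < thresholds$alpha_de
  pass_trans <- !is.na(it) & abs(de_trans$log2fc[it]) >= thresholds$trans_log2fc_min &
    de_trans$q_value[it] < thresholds$alpha_de
  concordant <- !is.na(ip) & !is.na(it) &
    sign(de_prot$log2fc[ip]) == sign(de_trans$log2fc[it])
  pass_prot[is.na(pass_prot)] <- FALSE
  pass_trans[is.na(pass_trans)] <- FALSE

  selected <- pass_corr & pass_prot & pass_trans &
    (!thresholds$require_concordant_direction | concordant) &
    !(genes %in% dropped)

  data.frame(gene_symbol = genes,
             rho = corrs$rho, p_corr = p_corr,
             log2fc_prot = de_prot$log2fc[ip], q_prot = de_prot$q_value[ip],
             log2fc_trans = de_trans$log2fc[it], q_trans = de_trans$q_value[it],
             pass_correlation = pass_corr, pass_proteome = pass_prot,
             pass_transcriptome = pass_trans, concordant = concordant,
             selected = selected,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Restrict DE and correlation results to an immunoglobulin isotype panel
#'
#' Produces the per-isotype summary used for constant-region heatmaps: the
#' rows of the two differential-expression tables and the correlation table
#' restricted to the panel. No new statistics are computed. Panel members that
#' do not resolve in the pair map are listed in the `missing` attribute rather
#' than raising an error.
#'
#' @param de_prot,de_trans,corrs full-result tables carrying `gene_symbol`.
#' @param isotype_ids character vector of panel gene symbols.
#' @return data.frame with one row per resolved panel member; attribute
#'   `missing` names the unresolved ids.
#' @export
isotype_panel_summary <- function(de_prot, de_trans, corrs, isotype_ids) {
  found <- intersect(isotype_ids, corrs$gene_symbol)
  missing <- setdiff(isotype_ids, found)
  ic <- match(found, corrs$gene_symbol)
  ip <- match(found, de_prot$gene_symbol)
  it <- match(found, de_trans$gene_symbol)
  out <- data.frame(gene_symbol = found,
                    rho = corrs$rho[ic], p_corr = corrs$p_value[ic],
                    log2fc_prot = de_prot$log2fc[ip],
                    p_prot = de_prot$p_value[ip], q_prot = de_prot$q_value[ip],
                    log2fc_trans = de_trans$log2fc[it],
                    p_trans = de_trans$p_value[it], q_trans = de_trans$q_value[it],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "missing") <- missing
  out
}
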