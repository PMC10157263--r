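# Paired-omics simulator: a serum proteome layer and a tissue transcriptome
# layer over partially overlapping case-control cohorts, with a configurable
# number of planted tumour-derived markers that are (i) up-regulated in cases
# in both layers and (ii) correlated across layers through a shared
# per-subject latent factor.

#' Configuration for the paired-omics simulator
#'
#' Defaults mirror the study design the package targets: a proteomic cohort of
#' 28 cases and 30 controls, a transcriptomic cohort of 38 cases and 31
#' controls, 1003 mapped protein-mRNA pairs, and one planted tumour-derived
#' marker whose proteomic effect size (log2 fold change 2.64) matches the
#' strongest serum marker reported in this design. Cross-layer correlation is
#' targeted on the Spearman scale.
#'
#' @param n_cases,n_controls proteome-layer group sizes.
#' @param n_cases_trans,n_controls_trans transcriptome-layer group sizes.
#' @param n_pairs number of mapped protein-mRNA pairs.
#' @param n_planted number of planted tumour-derived markers.
#' @param planted_log2fc_prot,planted_log2fc_trans expected case-control log2
#'   fold change of planted markers in each layer.
#' @param cross_omics_rho target Spearman correlation of planted markers
#'   across layers, in \[0, 1\].
#' @param shared_subject_fraction fraction of the smaller layer's subjects (per
#'   class) measured in both layers; must be in (0, 1\]. The default 0.76 is
#'   the overlap implied by 83 unique subjects filling 58 + 69 cohort slots.
#' @param noise_sd residual standard deviation on the log2 scale.
#' @param seed integer seed; generation is a pure function of the config.
#' @return an object of class `omics_sim_config`.
#' @export
omics_sim_config <- function(n_cases = 28, n_controls = 30,
                             n_cases_trans = 38, n_controls_trans = 31,
                             n_pairs = 1003, n_planted = 1,
                             planted_log2fc_prot = 2.64,
                             planted_log2fc_trans = 2.0,
                             cross_omics_rho = 0.6,
                             shared_subject_fraction = 0.76,
                             noise_sd = 0.8, seed = 1L) {
  cfg <- list(
    n_cases = assert_count(n_cases, "n_cases"),
    n_controls = assert_count(n_controls, "n_controls"),
    n_cases_trans = assert_count(n_cases_trans, "n_cases_trans"),
    n_controls_trans = assert_count(n_controls_trans, "n_controls_trans"),
    n_pairs = assert_count(n_pairs, "n_pairs"),
    n_planted = assert_count(n_planted, "n_planted", min = 0L),
    planted_log2fc_prot = as.numeric(planted_log2fc_prot),
    planted_log2fc_trans = as.numeric(planted_log2fc_trans),
    cross_omics_rho = assert_prob(cross_omics_rho, "cross_omics_rho"),
    shared_subject_fraction = as.numeric(shared_subject_fraction),
    noise_sd = assert_pos(noise_sd, "noise_sd"),
    seed = as.integer(seed)
  )
  if (cfg$n_planted > cfg$n_pairs)
    stop("n_planted must not exceed n_pairs", call. = FALSE)
  if (cfg$shared_subject_fraction <= 0 || cfg$shared_subject_fraction > 1)
    stop("shared_subject_fraction must be in (0, 1]", call. = FALSE)
  structure(cfg, class = "omics_sim_config")
}

# Spearman -> Pearson target for a bivariate normal latent scale
.pearson_for_spearman <- function(rho_s) 2 * sin(pi * rho_s / 6)

#' Generate a paired proteome/transcriptome data set
#'
#' Simulates abundances as `2^(baseline + class effect + latent + noise)`.
#' Planted markers carry the configured per-layer log2 fold change and a
#' per-subject latent factor shared between layers for subjects measured in
#' both, scaled so the cross-layer correlation of a planted marker approaches
#' `cross_omics_rho` (Spearman) over the shared subjects. Background features
#' have zero expected fold change and independent noise in the two layers.
#'
#' @param config an [omics_sim_config()].
#' @return a `paired_omics` object (see [paired_omics()]) with an extra
#'   element `planted` giving the gene symbols of the planted markers, and
#'   `case_ids` / `control_ids` per layer.
#' @export
generate_paired_omics <- function(config) {
  stopifnot(inherits(config, "omics_sim_config"))
  set.seed(substream_seed(config$seed, 11L))
  np <- config$n_pairs

  gene <- sprintf("G%04d", seq_len(np))
  prot_id <- sprintf("P%04d", seq_len(np))
  trans_id <- sprintf("T%04d", seq_len(np))

  # subject pool per class: shared subjects appear in both layers
  mk_ids <- function(class, n) sprintf("%s%03d", class, seq_len(n))
  n_sh_case <- max(1L, round(config$shared_subject_fraction *
                               min(config$n_cases, config$n_cases_trans)))
  n_sh_ctrl <- max(1L, round(config$shared_subject_fraction *
                               min(config$n_controls, config$n_controls_trans)))
  case_pool <- mk_ids("CASE", config$n_cases + config$n_cases_trans - n_sh_case)
  ctrl_pool <- mk_ids("CTRL", config$n_controls + config$n_controls_trans - n_sh_ctrl)

  shared_cases <- case_pool[seq_len(n_sh_case)]
  shared_ctrls <- ctrl_pool[seq_len(n_sh_ctrl)]
  prot_cases <- c(shared_cases,
                  case_pool[n_sh_case + seq_len(config$n_cases - n_sh_case)])
  trans_cases <- c(shared_cases,
                   case_pool[config$n_cases +
                               seq_len(config$n_cases_trans - n_sh_case)])
  prot_ctrls <- c(shared_ctrls,
                  ctrl_pool[n_sh_ctrl + seq_len(config$n_controls - n_sh_ctrl)])
  trans_ctrls <- c(shared_ctrls,
                   ctrl_pool[config$n_controls +
                               seq_len(config$n_controls_trans - n_sh_ctrl)])

  prot_sub <- c(prot_cases, prot_ctrls)
  trans_sub <- c(trans_cases, trans_ctrls)
  all_sub <- union(prot_sub, trans_sub)
  is_case <- stats::setNames(grepl("^CASE", all_sub), all_sub)

  planted_idx <- if (config$n_planted > 0) sort(sample.int(np, config$n_planted)) else integer(0)

  # variance decomposition: every feature keeps marginal log2 noise noise_sd;
  # planted features split theirs into a cross-layer shared latent component
  # (variance r_P * sd^2) and an idiosyncratic remainder, so the within-class
  # cross-layer Pearson correlation equals r_P (the Spearman target mapped
  # through the bivariate-normal relation)
  r_pearson <- .pearson_for_spearman(config$cross_omics_rho)
  a <- sqrt(r_pearson) * config$noise_sd
  resid_sd <- sqrt(1 - r_pearson) * config$noise_sd

  base_p <- stats::rnorm(np, mean = 5, sd = 1.5)
  base_t <- stats::rnorm(np, mean = 7, sd = 1.5)

  sim_layer <- function(base, subjects, fc, latent) {
    n <- length(subjects)
    m <- matrix(stats::rnorm(np * n, sd = config$noise_sd), nrow = np)
    if (length(planted_idx) && a > 0) {
      m[planted_idx, ] <- matrix(stats::rnorm(length(planted_idx) * n,
                                              sd = resid_sd),
                                 nrow = length(planted_idx)) +
        latent[planted_idx, subjects, drop = FALSE]
    }
    m <- m + base
    m[, is_case[subjects]] <- m[, is_case[subjects], drop = FALSE] +
      matrix(rep(fc, sum(is_case[subjects])), nrow = np)
    dimnames(m) <- list(NULL, subjects)
    m
  }

  latent <- matrix(0, nrow = np, ncol = length(all_sub),
                   dimnames = list(NULL, all_sub))
  if (length(planted_idx) && a > 0) {
    latent[planted_idx, ] <- matrix(stats::rnorm(length(planted_idx) *
                                                   length(all_sub), sd = a),
                                    nrow = length(planted_idx))
  }

  fc_p <- rep(0, np); fc_p[planted_idx] <- config$planted_log2fc_prot
  fc_t <- rep(0, np); fc_t[planted_idx] <- config$planted_log2fc_trans

  lp <- sim_layer(base_p, prot_sub, fc_p, latent)
  lt <- sim_layer(base_t, trans_sub, fc_t, latent)

  prot <- expression_matrix(2^lp, feature_ids = prot_id, subject_ids = prot_sub,
                            layer = "proteome")
  trans <- expression_matrix(2^lt, feature_ids = trans_id, subject_ids = trans_sub,
                             layer = "transcriptome")
  pm <- data.frame(protein_id = prot_id, transcript_id = trans_id,
                   gene_symbol = gene, stringsAsFactors = FALSE)
  po <- paired_omics(prot, trans, pm)
  po$planted <- gene[planted_idx]
  po$case_ids <- list(proteome = prot_cases, transcriptome = trans_cases)
  po$control_ids <- list(proteome = prot_ctrls, transcriptome = trans_ctrls)
  po
}
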