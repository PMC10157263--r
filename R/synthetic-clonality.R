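# Light-chain clonality simulator: per subject, a total immunoglobulin
# light-chain output split between kappa and lambda. Cases draw the dominant
# chain at random and give it an expected share equal to `restriction`;
# controls are balanced in expectation.

#' Configuration for the light-chain clonality simulator
#'
#' `restriction` is the expected share of total light-chain output carried by
#' the dominant chain in cases: 0.5 means balanced (polyclonal), 1 means fully
#' restricted (one chain only). The share is drawn from a Beta distribution
#' with mean exactly `restriction` and concentration `1 / noise_sd^2`, so the
#' expectation contract holds for every restriction level and the degenerate
#' `restriction = 1` collapses to a point mass.
#'
#' @param n_cases,n_controls group sizes.
#' @param restriction expected dominant-chain share in cases, in \[0.5, 1\].
#' @param total_ig_scale median total light-chain abundance (arbitrary units).
#' @param noise_sd log2-scale noise on the total output; also sets the
#'   dispersion of the share distribution.
#' @param seed integer seed.
#' @return an object of class `clonality_sim_config`.
#' @export
clonality_sim_config <- function(n_cases = 30, n_controls = 30,
                                 restriction = 0.9, total_ig_scale = 100,
                                 noise_sd = 0.5, seed = 1L) {
  if (!is.numeric(restriction) || restriction < 0.5 || restriction > 1)
    stop("restriction must be in [0.5, 1]", call. = FALSE)
  structure(list(
    n_cases = assert_count(n_cases, "n_cases"),
    n_controls = assert_count(n_controls, "n_controls"),
    restriction = as.numeric(restriction),
    total_ig_scale = assert_pos(total_ig_scale, "total_ig_scale"),
    noise_sd = assert_pos(noise_sd, "noise_sd"),
    seed = as.integer(seed)
  ), class = "clonality_sim_config")
}

.rbeta_mean <- function(n, mean, conc) {
  # Beta with given mean; degenerate endpoints handled exactly
  if (mean >= 1) return(rep(1, n))
  if (mean <= 0) return(rep(0, n))
  stats::rbeta(n, mean * conc, (1 - mean) * conc)
}

#' Generate per-subject kappa/lambda light-chain abundances
#'
#' @param config a [clonality_sim_config()].
#' @return data.frame with `subject_id`, `group` ("case"/"control"), `kappa`,
#'   `lambda`, `dominant` ("kappa"/"lambda"/NA for controls).
#' @export
generate_clonality <- function(config) {
  stopifnot(inherits(config, "clonality_sim_config"))
  set.seed(substream_seed(config$seed, 37L))
  n <- config$n_cases + config$n_controls
  group <- rep(c("case", "control"), c(config$n_cases, config$n_controls))
  conc <- 1 / config$noise_sd^2

  total <- config$total_ig_scale * 2^stats::rnorm(n, 0, config$noise_sd)
  share <- numeric(n)
  share[group == "case"] <- .rbeta_mean(config$n_cases, config$restriction, conc)
  share[group == "control"] <- .rbeta_mean(config$n_controls, 0.5, conc)

  dominant <- rep(NA_character_, n)
  dominant[group == "case"] <- ifelse(stats::runif(config$n_cases) < 0.5,
                                      "kappa", "lambda")
  # controls: the "dominant" label is arbitrary; assign kappa share directly
  kappa <- ifelse(is.na(dominant) | dominant == "kappa",
                  share * total, (1 - share) * total)
  lambda <- total - kappa

  data.frame(
    subject_id = sprintf("C%04d", seq_len(n)),
    group = group,
    kappa = kappa,
    lambda = lambda,
    dominant = dominant,
    stringsAsFactors = FALSE
  )
}
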