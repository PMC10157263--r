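# Case-control cohort simulator: four diagnosis classes (EMZL cases plus
# three control classes), log-normal serum IgM with a class shift, an
# age-dependent IgM decline confined to the control classes, and an optional
# post-treatment IgM decrease in cases.

#' Configuration for the case-control cohort simulator
#'
#' Defaults emulate the 205-patient four-class design: class sizes
#' (68, 33, 26, 78), a case/control shift in log serum IgM sized to give a
#' case-vs-control discrimination of about AUC 0.81, a negative IgM-age slope
#' confined to the control classes, younger cases on the age axis, a higher
#' lacrimal-gland involvement rate in cases, and an expected post-treatment
#' IgM decrease in cases.
#'
#' @param n_per_class integer vector of length 4: EMZL, other lymphoma,
#'   lymphoid hyperplasia, chronic inflammation.
#' @param igm_log_mean_case,igm_log_mean_control mean of log IgM (natural log,
#'   IgM in g/L) for cases / controls at the mean control age.
#' @param igm_log_sd standard deviation of log IgM.
#' @param age_igm_slope_controls slope of log IgM per year of age within the
#'   control classes (negative in this disease setting); cases have no age
#'   dependence.
#' @param age_mean_case,age_mean_control,age_sd age distribution (normal
#'   truncated to \[18, 90\]).
#' @param lacrimal_prob_case,lacrimal_prob_control probability of lacrimal
#'   gland involvement.
#' @param treatment_effect expected post-minus-pre IgM change in cases (g/L).
#' @param treated_fraction fraction of cases carrying a post-treatment value.
#' @param seed integer seed.
#' @return an object of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_per_class = c(68, 33, 26, 78),
                              igm_log_mean_case = 0.45,
                              igm_log_mean_control = -0.163,
                              igm_log_sd = 0.5,
                              age_igm_slope_controls = -0.01,
                              age_mean_case = 52, age_mean_control = 60,
                              age_sd = 15,
                              lacrimal_prob_case = 0.4,
                              lacrimal_prob_control = 0.15,
                              treatment_effect = -0.5,
                              treated_fraction = 0.6,
                              seed = 1L) {
  if (length(n_per_class) != 4L || any(n_per_class < 0) ||
      any(n_per_class != floor(n_per_class)))
    stop("n_per_class must be four non-negative integers", call. = FALSE)
  if (sum(n_per_class) == 0)
    stop("all class counts are zero", call. = FALSE)
  structure(list(
    n_per_class = as.integer(n_per_class),
    igm_log_mean_case = as.numeric(igm_log_mean_case),
    igm_log_mean_control = as.numeric(igm_log_mean_control),
    igm_log_sd = assert_pos(igm_log_sd, "igm_log_sd"),
    age_igm_slope_controls = as.numeric(age_igm_slope_controls),
    age_mean_case = as.numeric(age_mean_case),
    age_mean_control = as.numeric(age_mean_control),
    age_sd = assert_pos(age_sd, "age_sd"),
    lacrimal_prob_case = assert_prob(lacrimal_prob_case, "lacrimal_prob_case"),
    lacrimal_prob_control = assert_prob(lacrimal_prob_control, "lacrimal_prob_control"),
    treatment_effect = as.numeric(treatment_effect),
    treated_fraction = assert_prob(treated_fraction, "treated_fraction"),
    seed = as.integer(seed)
  ), class = "cohort_sim_config")
}

#' Diagnosis classes used throughout the package
#' @export
diagnosis_classes <- function() {
  c("EMZL", "other_lymphoma", "lymphoid_hyperplasia", "chronic_inflammation")
}

.rtruncnorm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Generate a synthetic case-control cohort table
#'
#' IgM is drawn log-normally per class. Within the three control classes the
#' conditional mean of log IgM declines with age at the configured slope
#' (centred at the control age mean so the marginal class mean is unchanged);
#' within cases IgM is independent of age. Each record carries sex, date of
#' diagnosis, bilateral involvement, disease site and lacrimal-gland
#' involvement; a seeded subset of cases carries a post-treatment IgM with
#' expected change `treatment_effect`.
#'
#' @param config a [cohort_sim_config()].
#' @return a data.frame cohort table (see [read_cohort()] for the column
#'   dictionary).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  set.seed(substream_seed(config$seed, 23L))
  classes <- diagnosis_classes()
  n <- sum(config$n_per_class)
  cls <- factor(rep(classes, times = config$n_per_class), levels = classes)
  is_case <- cls == "EMZL"

  age <- numeric(n)
  age[is_case] <- .rtruncnorm(sum(is_case), config$age_mean_case, config$age_sd, 18, 90)
  age[!is_case] <- .rtruncnorm(sum(!is_case), config$age_mean_control, config$age_sd, 18, 90)

  mu <- ifelse(is_case, config$igm_log_mean_case,
               config$igm_log_mean_control +
                 config$age_igm_slope_controls * (age - config$age_mean_control))
  igm <- exp(stats::rnorm(n, mean = mu, sd = config$igm_log_sd))

  # secondary immunoglobulins: no class effect (no diagnostic signal)
  iga <- exp(stats::rnorm(n, mean = log(2.2), sd = 0.4))
  igg <- exp(stats::rnorm(n, mean = log(11), sd = 0.3))
  ige <- exp(stats::rnorm(n, mean = log(0.05), sd = 0.8))

  sex <- factor(ifelse(stats::runif(n) < 0.5, "F", "M"), levels = c("F", "M"))
  date0 <- as.Date("2010-01-01")
  dod <- date0 + floor(stats::runif(n, 0, 3652))
  bilateral <- stats::runif(n) < ifelse(is_case, 0.15, 0.10)
  site_levels <- c("orbit", "conjunctiva", "eyelid", "lacrimal_gland")
  site <- factor(sample(site_levels, n, replace = TRUE,
                        prob = c(0.45, 0.25, 0.1, 0.2)), levels = site_levels)
  lacrimal <- stats::runif(n) < ifelse(is_case, config$lacrimal_prob_case,
                                       config$lacrimal_prob_control)

  post <- rep(NA_real_, n)
  treated <- is_case & stats::runif(n) < config$treated_fraction
  post[treated] <- pmax(igm[treated] + config$treatment_effect +
                          stats::rnorm(sum(treated), 0, 0.3), 0.02)

  ki67 <- rep(NA_real_, n)
  ki67[is_case] <- round(stats::runif(sum(is_case), 5, 40), 1)
  ann_arbor <- rep(NA_character_, n)
  ann_arbor[is_case] <- sample(c("I", "II", "III", "IV"), sum(is_case),
                               replace = TRUE, prob = c(0.6, 0.2, 0.1, 0.1))
  ipi <- rep(NA_character_, n)
  ipi[is_case] <- sample(c("0", "1", "2", "3+"), sum(is_case),
                         replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1))

  data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    diagnosis_class = cls,
    igm_g_per_l = igm,
    iga_g_per_l = iga,
    igg_g_per_l = igg,
    ige_g_per_l = ige,
    age_years = age,
    sex = sex,
    date_of_diagnosis = dod,
    bilateral = bilateral,
    disease_site = site,
    lacrimal_involvement = lacrimal,
    igm_post_treatment = post,
    ki67 = ki67,
    ann_arbor = ann_arbor,
    ipi = ipi,
    stringsAsFactors = FALSE
  )
}
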