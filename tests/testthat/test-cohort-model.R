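# Propensity matching, cohort analyses, logistic fitting, model selection,
# nomogram and validation split.

test_that("matching pairs opposite classes only, reports non-negative distances", {
  ch <- toy_cohort(n = 80, seed = 1)
  res <- propensity_match(ch, c("age_years", "sex"),
                          ch$diagnosis_class == "EMZL")
  expect_true(all(res$pairs$case_id %in%
                    ch$subject_id[ch$diagnosis_class == "EMZL"]))
  expect_true(all(res$pairs$control_id %in%
                    ch$subject_id[ch$diagnosis_class != "EMZL"]))
  expect_true(all(res$pairs$distance >= 0))
  # 1:1 without replacement
  expect_false(any(duplicated(res$pairs$control_id)))
  expect_false(any(duplicated(res$pairs$case_id)))
})

test_that("greedy matching follows the documented descending-propensity order", {
  # hand-traceable design: propensity driven by a single covariate
  ch <- data.frame(subject_id = paste0("s", 1:8),
                   x = c(5, 3, 1, 0.5, 4.4, 2.6, 1.2, 0.1),
                   stringsAsFactors = FALSE)
  case <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  res <- propensity_match(ch, "x", case)
  lp <- qlogis(res$propensity)
  # trace the greedy algorithm by hand on the propensity logits
  avail <- which(!case)
  expected <- character(0)
  for (i in order(-res$propensity[case])) {
    ci <- which(case)[i]
    j <- avail[which.min(abs(lp[avail] - lp[ci]))]
    expected <- c(expected, paste(ch$subject_id[ci], ch$subject_id[j]))
    avail <- setdiff(avail, j)
  }
  got <- paste(res$pairs$case_id, res$pairs$control_id)
  expect_equal(got, expected)
})

test_that("matching with the conventional caliper balances an injected age confounder", {
  ok <- vapply(1:10, function(s) {
    set.seed(s)
    n_case <- 300; n_ctrl <- 600
    ch <- data.frame(
      subject_id = sprintf("s%03d", 1:(n_case + n_ctrl)),
      age_years = c(rnorm(n_case, 61, 10), rnorm(n_ctrl, 55, 10)),
      sex = sample(c("F", "M"), n_case + n_ctrl, replace = TRUE),
      stringsAsFactors = FALSE)
    case <- rep(c(TRUE, FALSE), c(n_case, n_ctrl))
    res <- propensity_match(ch, c("age_years", "sex"), case, caliper = 0.2)
    abs(res$smd_before["age_years"]) > 0.5 &&
      abs(res$smd_after["age_years"]) < 0.2
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("excess cases are reported unmatched, not fatal", {
  ch <- data.frame(subject_id = paste0("s", 1:10),
                   age_years = rnorm(10, 50, 5), stringsAsFactors = FALSE)
  case <- rep(c(TRUE, FALSE), c(7, 3))
  res <- propensity_match(ch, "age_years", case)
  expect_equal(nrow(res$pairs), 3)
  expect_length(res$unmatched_cases, 4)
})

test_that("group tests adjust across contrasts and delta analysis matches oracles", {
  ch <- toy_cohort(n = 80, seed = 3)
  gt <- group_tests(ch)
  expect_equal(nrow(gt), 3)
  expect_equal(gt$q_value, p.adjust(gt$p_value, "BH"))

  # post = pre: delta 0, signed-rank p = 1
  ch$igm_post_treatment[ch$diagnosis_class == "EMZL"] <-
    ch$igm_g_per_l[ch$diagnosis_class == "EMZL"]
  da <- delta_igm_analysis(ch)
  expect_equal(da$per_group$median_delta, 0)
  expect_equal(da$per_group$p_value, 1)

  # signed-rank p equals exhaustive enumeration at n <= 10
  set.seed(5)
  for (rep in 1:6) {
    d <- round(rnorm(8, -0.3, 0.5), 3)
    p_pkg <- suppressWarnings(wilcox.test(d, mu = 0)$p.value)
    expect_equal(p_pkg, perm_signed_rank_p(d), tolerance = 1e-12)
  }
})

test_that("treatment effect in cases is detected by the one-sample test", {
  hits <- vapply(1:30, function(s) {
    ch <- generate_cohort(cohort_sim_config(n_per_class = c(40, 1, 1, 1),
                                            treatment_effect = -0.5,
                                            treated_fraction = 1, seed = s))
    da <- delta_igm_analysis(ch)
    da$per_group$p_value[da$per_group$group == "EMZL"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("confounder screen finds the control-only age correlation", {
  ch <- generate_cohort(cohort_sim_config(age_igm_slope_controls = -0.02,
                                          seed = 11))
  cs <- confounder_screen(ch)
  ctrl_rows <- cs$age_correlation$group != "EMZL"
  expect_true(all(cs$age_correlation$rho[ctrl_rows] < 0))
  expect_true(all(c("group", "p_value") %in% names(cs$sex_comparison)))
})

test_that("age cutoff lands in the gap for separated age distributions", {
  ch <- data.frame(subject_id = paste0("s", 1:40),
                   age_years = c(rnorm(20, 35, 3), rnorm(20, 70, 3)),
                   diagnosis_class = factor(rep(c("EMZL", "chronic_inflammation"),
                                                each = 20),
                                            levels = diagnosis_classes()),
                   stringsAsFactors = FALSE)
  ac <- age_cutoff(ch)
  expect_gt(ac$cutoff, max(ch$age_years[1:20]))
  expect_lte(ac$cutoff, min(ch$age_years[21:40]))
  expect_equal(ac$indicator, ch$age_years < ac$cutoff)
  expect_equal(ac$sensitivity, 1)
  expect_equal(ac$specificity, 1)
})

test_that("fit_logistic reproduces the closed-form log odds ratio on 2x2 tables", {
  for (a in c(1, 4, 9)) for (b in c(2, 7)) for (c_ in c(3, 8)) for (d in c(1, 6)) {
    X <- cbind(`(Intercept)` = 1, x = c(1, 1, 0, 0))
    y <- c(1, 0, 1, 0)
    fit <- fit_logistic(X, y, weights = c(a, b, c_, d))
    expect_equal(unname(fit$terms["x"]), log(a * d / (b * c_)), tolerance = 1e-8)
    expect_equal(fit$aic, 2 * 2 - 2 * fit$log_likelihood)
  }
})

test_that("fit_logistic agrees with glm and flags separation / collinearity", {
  set.seed(6)
  n <- 300
  X <- cbind(`(Intercept)` = 1, a = rnorm(n), b = rbinom(n, 1, 0.4))
  y <- rbinom(n, 1, plogis(-0.5 + X[, "a"] + 0.8 * X[, "b"]))
  fit <- fit_logistic(X, y)
  ref <- glm(y ~ a + b, data = data.frame(a = X[, "a"], b = X[, "b"]),
             family = binomial())
  expect_equal(unname(fit$terms), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(summary(ref)$coefficients[, 2]),
               tolerance = 1e-4)
  expect_equal(fit$aic, AIC(ref), tolerance = 1e-6)

  # complete separation: flagged, finite coefficients via ridge
  xs <- c(rnorm(20, -3), rnorm(20, 3))
  ys <- rep(c(0, 1), each = 20)
  fs <- fit_logistic(cbind(1, xs), ys)
  expect_true(fs$separated)
  expect_true(all(is.finite(fs$terms)))

  expect_error(fit_logistic(cbind(1, X[, "a"], 2 * X[, "a"]), y), "collinear")
})

test_that("null design yields coefficients within 3 SE of zero", {
  set.seed(7)
  n <- 2000
  X <- cbind(`(Intercept)` = 1, a = rnorm(n), b = rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, 0.3)
  fit <- fit_logistic(X, y)
  expect_true(all(abs(fit$terms[c("a", "b")]) <
                    3 * fit$se[c("a", "b")]))
})

test_that("select_model adds a strong candidate, skips none, equals base fit when empty", {
  set.seed(8)
  n <- 800
  d <- data.frame(x1 = rbinom(n, 1, 0.5), x2 = rbinom(n, 1, 0.5),
                  strong = rbinom(n, 1, 0.5))
  d$y <- rbinom(n, 1, plogis(-1 + d$x1 + 2 * d$strong))
  sel <- select_model(d, "y", base_terms = c("x1", "x2"),
                      candidate_terms = "strong")
  expect_equal(sel$included, "strong")
  expect_true(sel$report$included)

  sel0 <- select_model(d, "y", base_terms = c("x1", "x2"))
  direct <- fit_logistic(cbind(`(Intercept)` = 1, x1 = d$x1, x2 = d$x2), d$y)
  expect_identical(sel0$fit$terms, direct$terms)
  expect_equal(nrow(sel0$report), 0)
})

test_that("nomogram points are affine in the coefficients and reproduce model probabilities", {
  # single binary predictor: points are {0, 100}
  set.seed(9)
  x <- rbinom(200, 1, 0.5)
  y <- rbinom(200, 1, plogis(-1 + 1.4 * x))
  fit <- fit_logistic(cbind(`(Intercept)` = 1, x = x), y)
  nom <- build_nomogram(fit)
  tab <- nom$points_per_term$x
  expect_equal(tab$points, c(0, 100))
  expect_equal(nomogram_probability(nom, 100),
               unname(plogis(sum(fit$terms))), tolerance = 1e-12)

  # multi-term fit: equivalence at 1e-9 on random covariate patterns
  d <- data.frame(m = rbinom(300, 1, 0.4), h = rbinom(300, 1, 0.3),
                  a = rbinom(300, 1, 0.5))
  yy <- rbinom(300, 1, plogis(-2 + 1.0 * d$m + 2.2 * d$h + 0.9 * d$a))
  X <- cbind(`(Intercept)` = 1, as.matrix(d))
  fit2 <- fit_logistic(X, yy)
  nom2 <- build_nomogram(fit2)
  pat <- cbind(1, as.matrix(expand.grid(m = 0:1, h = 0:1, a = 0:1)))
  colnames(pat) <- colnames(X)
  expect_equal(nomogram_probability(nom2, nomogram_points(nom2, pat)),
               predict(fit2, pat), tolerance = 1e-9)
  # the largest coefficient range owns the 100-point span
  spans <- vapply(nom2$points_per_term, function(t) max(t$points), numeric(1))
  expect_equal(unname(which.max(spans)), 2)  # "h" has the largest |beta|
  expect_equal(max(spans), 100)
})

test_that("stratified split preserves class proportions and flags an empty validation set", {
  ch <- generate_cohort(cohort_sim_config(n_per_class = c(68, 33, 26, 78),
                                          seed = 13))
  sv <- split_and_validate(ch, 0.88, 1.46, 47, derivation_fraction = 0.6,
                           seed = 2)
  nd <- table(sv$derivation$diagnosis_class)
  nall <- table(ch$diagnosis_class)
  expect_true(all(abs(nd - 0.6 * nall) <= 1))
  expect_equal(nrow(sv$derivation) + nrow(sv$validation), nrow(ch))
  expect_warning(split_and_validate(ch, 0.88, 1.46, 47,
                                    derivation_fraction = 1, seed = 2),
                 "empty")
  # reproducible split
  sv2 <- split_and_validate(ch, 0.88, 1.46, 47, derivation_fraction = 0.6,
                            seed = 2)
  expect_identical(sv$split, sv2$split)
})

test_that("the combined model outscores ordinal IgM alone when age/lacrimal carry signal", {
  wins <- vapply(1:25, function(s) {
    ch <- generate_cohort(cohort_sim_config(seed = s))
    sv <- split_and_validate(ch, 0.88, 1.46, 47, seed = s)
    with(sv$aucs[sv$aucs$set == "derivation", ],
         model_auc >= ordinal_auc - 1e-9)
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("calibration: one bin reproduces prevalence; miscalibration is visible", {
  set.seed(14)
  n <- 600
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.5 + x))
  fit <- fit_logistic(cbind(`(Intercept)` = 1, x = x), y)
  cal1 <- calibration_assess(fit, n_bins = 1)
  expect_equal(nrow(cal1), 1)
  expect_equal(cal1$observed, mean(y))

  cal <- calibration_assess(fit, n_bins = 10)
  expect_lt(max(abs(cal$observed - cal$mean_predicted)), 0.15)

  # logit shifted +1: systematic deviation
  bad <- fit
  bad$fitted <- plogis(qlogis(fit$fitted) + 1)
  calb <- calibration_assess(bad, n_bins = 10)
  expect_gt(mean(calb$mean_predicted - calb$observed), 0.1)

  # bootstrap-corrected curve exists and is finite
  calboot <- calibration_assess(fit, n_bins = 5, bootstrap_reps = 30, seed = 3)
  expect_true(all(is.finite(calboot$observed_corrected)))
})
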