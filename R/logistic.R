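# Logistic modelling layer: a design-matrix fit (maximum likelihood via
# stats::glm.fit, with a ridge-penalized IRLS fallback for separated data),
# AIC-guided forward inclusion of candidate predictors, and the points-based
# nomogram re-expression of a fitted model.

#' Fit a logistic regression on an explicit design matrix
#'
#' Maximum-likelihood fit with Wald standard errors and p-values. The design
#' must be full column rank (an error names the collinear columns otherwise).
#' Complete or quasi-complete separation is detected from diverging
#' coefficients / degenerate fitted probabilities; the model is then refit
#' with a small ridge penalty on the non-intercept coefficients and flagged.
#'
#' @param design numeric design matrix including the intercept column if one
#'   is wanted (a column named `(Intercept)` or a constant column).
#' @param outcome 0/1 or logical outcome vector.
#' @param weights optional case weights (e.g. contingency-table counts).
#' @param ridge_on_separation ridge penalty applied only on separation
#'   (default 1e-6); set to a positive value via `ridge` to force a penalized
#'   fit.
#' @param ridge optional penalty applied unconditionally.
#' @return an object of class `logistic_fit`: `terms` (named coefficients),
#'   `se`, `p_values`, `log_likelihood`, `aic`, `converged`, `separated`,
#'   `design`, `outcome`, `weights`, `fitted`.
#' @export
fit_logistic <- function(design, outcome, weights = NULL,
                         ridge_on_separation = 1e-6, ridge = 0) {
  X <- as.matrix(design)
  if (is.null(colnames(X)))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(ncol(X) - 1)))[seq_len(ncol(X))]
  y <- as.numeric(as.logical(outcome))
  w <- weights %||% rep(1, length(y))
  stopifnot(nrow(X) == length(y), length(w) == length(y))

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])]
    stop("design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  separated <- FALSE
  if (ridge > 0) {
    fit <- .ridge_irls(X, y, w, ridge)
  } else {
    fit <- suppressWarnings(stats::glm.fit(X, y, weights = w,
                                           family = stats::binomial(),
                                           control = stats::glm.control(
                                             epsilon = 1e-12, maxit = 100)))
    # diverging coefficients are the signature of (quasi-)separation
    sep <- any(abs(fit$coefficients) > 15)
    if (!fit$converged || sep) {
      separated <- TRUE
      fit <- .ridge_irls(X, y, w, ridge_on_separation)
    }
  }

  beta <- fit$coefficients
  mu <- as.numeric(stats::plogis(X %*% beta))
  ll <- sum(w * (y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300))))
  Wd <- w * mu * (1 - mu)
  info <- crossprod(X, X * Wd)
  cov <- tryCatch(solve(info), error = function(e) {
    solve(info + diag(1e-8, ncol(X)))
  })
  se <- sqrt(pmax(diag(cov), 0))
  z <- beta / se
  k <- ncol(X)
  structure(list(terms = stats::setNames(as.numeric(beta), colnames(X)),
                 se = stats::setNames(se, colnames(X)),
                 p_values = stats::setNames(2 * stats::pnorm(-abs(z)), colnames(X)),
                 log_likelihood = ll,
                 aic = 2 * k - 2 * ll,
                 converged = isTRUE(fit$converged) || separated,
                 separated = separated,
                 design = X, outcome = y, weights = w, fitted = mu),
            class = "logistic_fit")
}

# penalized IRLS: ridge on all non-constant columns, excluded for columns
# that are constant across rows (intercept)
.ridge_irls <- function(X, y, w, lambda, tol = 1e-10, maxit = 100L) {
  k <- ncol(X)
  pen <- diag(rep(lambda, k))
  is_const <- apply(X, 2L, function(col) length(unique(col)) == 1L)
  diag(pen)[is_const] <- 0
  beta <- rep(0, k)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- as.numeric(X %*% beta)
    mu <- stats::plogis(eta)
    Wd <- pmax(w * mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / pmax(mu * (1 - mu), 1e-12)
    H <- crossprod(X, X * Wd) + pen
    beta <- as.numeric(solve(H, crossprod(X, Wd * z)))
    ll <- sum(w * (y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))) -
      0.5 * sum(diag(pen) * beta^2)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(coefficients = stats::setNames(beta, colnames(X)), converged = converged)
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> %d terms, logLik = %.3f, AIC = %.3f%s\n",
              length(x$terms), x$log_likelihood, x$aic,
              if (x$separated) " (ridge fallback: separation)" else ""))
  tab <- data.frame(coef = x$terms, se = x$se, p = x$p_values)
  print(round(tab, 4))
  invisible(x)
}

#' Predicted probabilities from a logistic fit
#' @param object a `logistic_fit`.
#' @param newdesign design matrix with the fit's columns; default the training
#'   design.
#' @param ... unused.
#' @return numeric probabilities.
#' @export
predict.logistic_fit <- function(object, newdesign = NULL, ...) {
  X <- if (is.null(newdesign)) object$design else as.matrix(newdesign)
  as.numeric(stats::plogis(X %*% object$terms[colnames(object$design)]))
}

#' AIC-guided forward inclusion of candidate predictors
#'
#' Starting from the base terms, each candidate column (in the listed order)
#' is added to the model if and only if adding it lowers the AIC of the
#' current model. Evaluation order is deterministic.
#'
#' @param data data.frame holding all columns.
#' @param outcome_col name of the 0/1 outcome column.
#' @param base_terms column names always included.
#' @param candidate_terms column names tried in order.
#' @return list with `fit` (the final [fit_logistic()]), `included` (candidate
#'   names kept), `report` (data.frame of candidate, AIC without/with,
#'   included).
#' @export
select_model <- function(data, outcome_col, base_terms, candidate_terms = character(0)) {
  build <- function(terms) {
    X <- cbind(`(Intercept)` = 1,
               as.matrix(as.data.frame(lapply(data[terms], as.numeric))))
    colnames(X) <- c("(Intercept)", terms)
    X
  }
  y <- data[[outcome_col]]
  current <- base_terms
  fit <- fit_logistic(build(current), y)
  rows <- list()
  for (cand in candidate_terms) {
    trial <- fit_logistic(build(c(current, cand)), y)
    take <- trial$aic < fit$aic
    rows[[cand]] <- data.frame(candidate = cand, aic_without = fit$aic,
                               aic_with = trial$aic, included = take,
                               stringsAsFactors = FALSE)
    if (take) {
      current <- c(current, cand)
      fit <- trial
    }
  }
  list(fit = fit, included = setdiff(current, base_terms),
       report = if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
       else data.frame(candidate = character(0), aic_without = numeric(0),
                       aic_with = numeric(0), included = logical(0)))
}

#' Points-based nomogram from a logistic fit
#'
#' Re-expresses a fitted logistic model on a 0-100 points scale: each term's
#' contribution `beta * x` is anchored at its observed minimum and scaled so
#' the term with the widest contribution range spans 100 points. Total points
#' map back to predicted probability through the inverse logit, so nomogram
#' probabilities equal model probabilities exactly.
#'
#' @param fit a [fit_logistic()] result (its stored design supplies the
#'   observed value ranges).
#' @return an object of class `nomogram`: `points_per_term` (per-term value ->
#'   points tables for discrete terms, slope/anchor for continuous),
#'   `scale` (points per unit of linear predictor), `offset`, `fit`.
#' @export
build_nomogram <- function(fit) {
  stopifnot(inherits(fit, "logistic_fit"))
  X <- fit$design
  beta <- fit$terms
  termcols <- setdiff(colnames(X), "(Intercept)")
  if (!length(termcols)) stop("nomogram needs at least one predictor", call. = FALSE)
  contrib_min <- vapply(termcols, function(j) min(beta[j] * X[, j]), numeric(1))
  contrib_max <- vapply(termcols, function(j) max(beta[j] * X[, j]), numeric(1))
  ranges <- contrib_max - contrib_min
  L <- max(ranges)
  if (L <= 0) stop("all predictors are constant", call. = FALSE)

  points_per_term <- lapply(termcols, function(j) {
    vals <- sort(unique(X[, j]))
    pts <- (beta[j] * vals - contrib_min[j]) * 100 / L
    if (length(vals) <= 12) {
      data.frame(value = vals, points = pts)
    } else {
      list(slope = beta[j] * 100 / L, anchor = contrib_min[j] * 100 / L,
           range = range(vals))
    }
  })
  names(points_per_term) <- termcols

  intercept <- if ("(Intercept)" %in% colnames(X)) beta["(Intercept)"] else 0
  offset <- unname(intercept + sum(contrib_min))
  structure(list(points_per_term = points_per_term,
                 scale = L / 100, offset = offset,
                 term_order = termcols, fit = fit),
            class = "nomogram")
}

#' Total points for covariate rows, and probability from total points
#'
#' @param nomogram a [build_nomogram()] object.
#' @param newdesign design matrix rows (same columns as the underlying fit).
#' @return `nomogram_points()`: numeric total points per row.
#' @export
nomogram_points <- function(nomogram, newdesign) {
  X <- as.matrix(newdesign)
  beta <- nomogram$fit$terms
  tc <- nomogram$term_order
  contrib_min <- vapply(tc, function(j)
    min(beta[j] * nomogram$fit$design[, j]), numeric(1))
  pts <- vapply(tc, function(j)
    (beta[j] * X[, j] - contrib_min[j]) / nomogram$scale, numeric(nrow(X)))
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = nrow(X))
  rowSums(pts)
}

#' @rdname nomogram_points
#' @param total_points numeric total points.
#' @return `nomogram_probability()`: predicted probability for a total-points
#'   value.
#' @export
nomogram_probability <- function(nomogram, total_points) {
  stats::plogis(nomogram$offset + total_points * nomogram$scale)
}

#' @export
print.nomogram <- function(x, ...) {
  cat("<nomogram> points per term:\n")
  for (nm in x$term_order) {
    tab <- x$points_per_term[[nm]]
    if (is.data.frame(tab)) {
      cat(sprintf("  %s: %s\n", nm,
                  paste(sprintf("%g -> %.1f", tab$value, tab$points),
                        collapse = ", ")))
    } else {
      cat(sprintf("  %s: %.2f points per unit\n", nm, tab$slope))
    }
  }
  invisible(x)
}
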