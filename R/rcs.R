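# Restricted cubic splines inside a logistic model: the natural-spline basis
# in the truncated-power parameterization, a likelihood-ratio test of
# linearity, and the minimal-AIC dichotomization scan that turns a continuous
# marker into a clinical cutoff.

#' Restricted cubic spline (natural spline) basis
#'
#' For k strictly increasing knots `t1 < ... < tk` returns `k - 1` design
#' columns: the linear term plus `k - 2` restricted cubic terms in the
#' truncated-power parameterization,
#' `((x-tj)+^3 - (x-t(k-1))+^3 (tk-tj)/(tk-t(k-1)) + (x-tk)+^3 (t(k-1)-tj)/(tk-t(k-1))) / (tk-t1)^2`.
#' The resulting function space is continuous with continuous first and
#' second derivatives and exactly linear beyond the boundary knots.
#'
#' @param x numeric vector.
#' @param knots at least 3 strictly increasing knot locations.
#' @return matrix with `length(knots) - 1` columns named `x`, `x1`, `x2`, ...
#' @export
rcs_basis <- function(x, knots) {
  knots <- as.numeric(knots)
  if (anyDuplicated(knots)) stop("duplicate knots", call. = FALSE)
  knots <- sort(knots)
  if (length(knots) < 3) stop("need at least 3 distinct knots", call. = FALSE)
  k <- length(knots)
  tk <- knots[k]; tk1 <- knots[k - 1]; t1 <- knots[1]
  pp3 <- function(u) pmax(u, 0)^3
  cols <- lapply(seq_len(k - 2), function(j) {
    tj <- knots[j]
    (pp3(x - tj) -
       pp3(x - tk1) * (tk - tj) / (tk - tk1) +
       pp3(x - tk) * (tk1 - tj) / (tk - tk1)) / (tk - t1)^2
  })
  out <- cbind(x, do.call(cbind, cols))
  colnames(out) <- c("x", if (k > 2) paste0("x", seq_len(k - 2)))
  out
}

#' Default knot locations at standard quantiles
#'
#' 3 knots at (10, 50, 90)%, 4 knots at (5, 35, 65, 95)%, 5 knots at
#' (5, 27.5, 50, 72.5, 95)% — the conventional placements for restricted
#' cubic splines.
#'
#' @param x numeric data vector.
#' @param n_knots 3, 4 (default) or 5.
#' @return numeric knot locations.
#' @export
default_knots <- function(x, n_knots = 4L) {
  probs <- switch(as.character(n_knots),
                  "3" = c(0.10, 0.50, 0.90),
                  "4" = c(0.05, 0.35, 0.65, 0.95),
                  "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
                  stop("n_knots must be 3, 4 or 5", call. = FALSE))
  unname(stats::quantile(x, probs, type = 7))
}

#' Likelihood-ratio test of linearity via restricted cubic splines
#'
#' Fits logistic models `y ~ rcs(x)` and `y ~ x` and tests the nonlinear
#' spline coefficients with a likelihood-ratio chi-square on `k - 2` degrees
#' of freedom. A small p-value says the predictor's effect on the log-odds is
#' nonlinear.
#'
#' @param x continuous predictor.
#' @param y_binary 0/1 or logical outcome.
#' @param knots knot locations; default [default_knots()] with 4 knots.
#' @return an object of class `rcs_fit`: `knots`, `coefficients`,
#'   `log_likelihood`, `aic`, `p_nonlinearity`, `lrt_stat`, `df`.
#' @export
nonlinearity_test <- function(x, y_binary, knots = NULL) {
  y <- as.integer(as.logical(y_binary))
  knots <- knots %||% default_knots(x, 4L)
  B <- rcs_basis(x, knots)
  full <- stats::glm(y ~ B, family = stats::binomial())
  lin <- stats::glm(y ~ x, family = stats::binomial())
  ll_full <- as.numeric(stats::logLik(full))
  ll_lin <- as.numeric(stats::logLik(lin))
  df <- length(knots) - 2L
  lrt <- max(0, 2 * (ll_full - ll_lin))
  p <- if (df > 0) stats::pchisq(lrt, df, lower.tail = FALSE) else 1
  structure(list(knots = knots,
                 coefficients = stats::coef(full),
                 log_likelihood = ll_full,
                 aic = 2 * length(stats::coef(full)) - 2 * ll_full,
                 p_nonlinearity = p, lrt_stat = lrt, df = df,
                 linear_log_likelihood = ll_lin),
            class = "rcs_fit")
}

#' @export
print.rcs_fit <- function(x, ...) {
  cat(sprintf("<rcs_fit> %d knots; LRT chi2 = %.3f on %d df, p(nonlinearity) = %.4g\n",
              length(x$knots), x$lrt_stat, x$df, x$p_nonlinearity))
  invisible(x)
}

#' Minimal-AIC dichotomization scan
#'
#' For each candidate cutoff `c` in the grid, fits the logistic model
#' `y ~ 1[x >= c]` and returns the cutoff minimizing the AIC (ties broken
#' toward the smaller cutoff). The default grid is the unique observed values
#' between the 5th and 95th percentiles. Complete separation at a grid point
#' is detected and handled with a small ridge penalty on the slope.
#'
#' @param x continuous marker.
#' @param y_binary 0/1 or logical outcome.
#' @param grid candidate cutoffs; default as above.
#' @param ridge penalty used only when a fit separates (default 1e-6).
#' @return list with `aic_cutoff`, `aic_value`, `scan` (data.frame of the full
#'   grid), `intercept_aic`, `separated` (cutoffs where ridge was applied).
#' @export
aic_cutoff_scan <- function(x, y_binary, grid = NULL, ridge = 1e-6) {
  y <- as.integer(as.logical(y_binary))
  if (is.null(grid)) {
    q <- stats::quantile(x, c(0.05, 0.95), type = 7)
    grid <- sort(unique(x[x >= q[1] & x <= q[2]]))
  }
  grid <- sort(unique(grid))
  if (!length(grid)) stop("empty cutoff grid", call. = FALSE)
  separated <- numeric(0)
  aics <- vapply(grid, function(cc) {
    d <- as.integer(x >= cc)
    if (length(unique(d)) == 1L) {
      f0 <- stats::glm(y ~ 1, family = stats::binomial())
      return(2 * 2 - 2 * as.numeric(stats::logLik(f0)))  # wasted df on a constant column
    }
    fit <- fit_logistic(cbind(1, d), y, ridge_on_separation = ridge)
    if (fit$separated) separated <<- c(separated, cc)
    fit$aic
  }, numeric(1))
  best <- min(aics)
  i <- which(aics <= best + 1e-9)[1]  # grid sorted: first index is smallest cutoff
  f0 <- stats::glm(y ~ 1, family = stats::binomial())
  list(aic_cutoff = grid[i], aic_value = aics[i],
       scan = data.frame(cutoff = grid, aic = aics),
       intercept_aic = 2 * 1 - 2 * as.numeric(stats::logLik(f0)),
       separated = separated)
}
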