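#' Classical-nucleation-theory line fit result
#'
#' Slope and intercept of the line `ddG = b + s x`,
#' `x = n^(2/3) - (n-1)^(2/3)`: the intercept `b` is the chemical-potential
#' difference between the infinite cluster (bulk phase) and the reservoir
#' gas, and the slope is related to the surface tension by
#' `s = (36 pi / rho^2)^(1/3) gamma`.
#'
#' @param slope,intercept Fitted coefficients.
#' @param se_slope,se_intercept Their standard errors (>= 0).
#' @param range Fitted size range (length 2).
#' @param weighted Whether weights `1/se^2` were used.
#' @param n_points Number of fitted points.
#' @param cov Optional 2x2 parameter covariance (intercept, slope).
#' @return An object of class `cnt_fit`.
#' @export
cnt_fit <- function(slope, intercept, se_slope = 0, se_intercept = 0,
                    range = c(NA, NA), weighted = NA, n_points = NA,
                    cov = NULL) {
  stopifnot(se_slope >= 0, se_intercept >= 0)
  structure(list(slope = slope, intercept = intercept, se_slope = se_slope,
                 se_intercept = se_intercept, range = range,
                 weighted = weighted, n_points = n_points, cov = cov),
            class = "cnt_fit")
}

#' @export
print.cnt_fit <- function(x, ...) {
  cat(sprintf(
    "CNT line fit (%s, %s points, sizes %s..%s):\n  slope = %.4f +- %.4f\n  intercept = %.4f +- %.4f\n",
    if (isTRUE(x$weighted)) "weighted" else "unweighted", x$n_points,
    x$range[1], x$range[2], x$slope, x$se_slope, x$intercept,
    x$se_intercept))
  invisible(x)
}

#' Fit the free-energy increments to the CNT line
#'
#' Least squares of `ddg` on `x = n^(2/3) - (n-1)^(2/3)`. With `weighted =
#' TRUE` and finite errors, weights are `1/se^2` and the parameter errors
#' come from the unscaled covariance `(X' W X)^(-1)` (the stated errors are
#' taken at face value); without usable errors the fit falls back to
#' ordinary least squares with residual-scaled errors.
#'
#' @param series A `delta_g_series` from [delta_g_series()] (or any data
#'   frame with columns `n`, `x`, `ddg` and optionally `se`).
#' @param range Optional inclusive size range `c(n_lo, n_hi)` to fit.
#' @param weighted Use inverse-variance weights when errors are available.
#' @return A [cnt_fit()].
#' @export
fit_delta_g <- function(series, range = NULL, weighted = TRUE) {
  d <- as.data.frame(series)
  if (!is.null(range)) d <- d[d$n >= range[1] & d$n <= range[2], ]
  if (nrow(d) < 3) stop("need at least 3 points to fit the CNT line")
  use_w <- weighted && !is.null(d$se) && all(is.finite(d$se)) &&
    all(d$se > 0)
  X <- cbind(1, d$x)
  if (use_w) {
    w <- 1 / d$se^2
    xtwx <- crossprod(X * sqrt(w))
    v <- solve(xtwx)
    coefs <- v %*% crossprod(X * w, d$ddg)
    se <- sqrt(diag(v))
    cov <- v
  } else {
    fit <- stats::lm(ddg ~ x, data = d)
    coefs <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    cov <- stats::vcov(fit)
  }
  cnt_fit(slope = coefs[2], intercept = coefs[1], se_slope = se[2],
          se_intercept = se[1],
          range = c(min(d$n), max(d$n)), weighted = use_w,
          n_points = nrow(d), cov = cov)
}

#' Surface tension from the CNT slope
#'
#' `gamma = s / (36 pi / rho^2)^(1/3)`, where `rho` is the bulk-phase
#' number density. Errors are propagated from both the slope and the
#' density.
#'
#' @param fit A [cnt_fit()].
#' @param rho Bulk number density (> 0).
#' @param rho_se Its standard error.
#' @return List with `gamma` and `se`.
#' @export
surface_tension <- function(fit, rho, rho_se = 0) {
  stopifnot(rho > 0)
  fac <- (36 * pi / rho^2)^(1 / 3)
  gamma <- fit$slope / fac
  se <- sqrt((fit$se_slope / fac)^2 + ((2 / 3) * gamma / rho * rho_se)^2)
  list(gamma = gamma, se = se)
}

#' Bulk chemical potential from the CNT intercept
#'
#' The intercept is the chemical-potential difference between the bulk
#' phase and the reservoir gas, so `mu_bulk = b + T ln(n_v)` (kinetic term
#' excluded by convention; at `n_v = 1` the reservoir chemical potential is
#' zero and `mu_bulk = b`).
#'
#' @param fit A [cnt_fit()].
#' @param reservoir A [reservoir_spec()].
#' @return List with `mu` and `se`.
#' @export
chemical_potential <- function(fit, reservoir) {
  list(mu = fit$intercept + reservoir$mu_gas, se = fit$se_intercept)
}
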