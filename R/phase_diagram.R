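#' A coexistence point in the phase diagram
#'
#' @param temperature,pressure Location (reduced units).
#' @param label `"melting"` or `"triple"`.
#' @param t_se,p_se Uncertainties.
#' @return An object of class `phase_point`.
#' @export
phase_point <- function(temperature, pressure = NA_real_,
                        label = c("melting", "triple"), t_se = 0, p_se = 0) {
  stopifnot(temperature > 0)
  structure(list(temperature = temperature, pressure = pressure,
                 label = match.arg(label), t_se = t_se, p_se = p_se),
            class = "phase_point")
}

#' @export
print.phase_point <- function(x, ...) {
  cat(sprintf("%s point: T = %.4f +- %.4f%s\n", x$label, x$temperature,
              x$t_se,
              if (is.finite(x$pressure))
                sprintf(", P = %.3g +- %.2g", x$pressure, x$p_se) else ""))
  invisible(x)
}

#' Two-phase coexistence curve
#'
#' @param temperature,pressure Parallel vectors; temperature strictly
#'   increasing.
#' @param label `"SL"` (solid-liquid) or `"LV"` (liquid-vapor).
#' @return An object of class `coexistence_curve` (a data frame).
#' @export
coexistence_curve <- function(temperature, pressure, label = c("SL", "LV")) {
  stopifnot(length(temperature) == length(pressure),
            all(diff(temperature) > 0))
  structure(data.frame(T = temperature, P = pressure),
            label = match.arg(label),
            class = c("coexistence_curve", "data.frame"))
}

#' Read a coexistence curve from a TSV file
#'
#' Expects a header with columns `T` and `P` (reduced units).
#'
#' @param path File path.
#' @param label Curve label.
#' @return A [coexistence_curve()].
#' @export
read_coexistence_curve <- function(path, label = "LV") {
  d <- utils::read.table(path, header = TRUE)
  coexistence_curve(d$T, d$P, label)
}

# linear interpolation with linear extrapolation from the end slopes
.interp_extrap <- function(x, y, xout) {
  ord <- order(x)
  x <- x[ord]
  y <- y[ord]
  out <- stats::approx(x, y, xout = xout, rule = 2)$y
  if (length(x) >= 2) {
    lo <- xout < x[1]
    hi <- xout > x[length(x)]
    s_lo <- (y[2] - y[1]) / (x[2] - x[1])
    s_hi <- (y[length(y)] - y[length(y) - 1]) / (x[length(x)] - x[length(x) - 1])
    out[lo] <- y[1] + s_lo * (xout[lo] - x[1])
    out[hi] <- y[length(y)] + s_hi * (xout[hi] - x[length(x)])
  }
  out
}

#' Propagate a chemical potential in temperature (Gibbs-Helmholtz)
#'
#' At fixed pressure, `d(beta mu)/d(beta) = h`, the enthalpy per particle,
#' so `beta mu(T) = beta0 mu0 + integral of h d(beta)`. The enthalpy is
#' interpolated linearly in `beta = 1/T` between tabulated state points
#' (linear end-slope extrapolation just outside the table) and the
#' integral uses the trapezoidal rule with step at most `max_step` in
#' `beta`.
#'
#' @param mu0 Chemical potential at the reference temperature `t0`.
#' @param t0 Reference temperature.
#' @param h_table Data frame with columns `T` and `h` (enthalpy per
#'   particle); an optional `h_se` column feeds uncertainty resampling in
#'   [melting_point()].
#' @param temperature Target temperature(s).
#' @param max_step Maximum `beta` step of the quadrature.
#' @return `mu(temperature)` (vectorized).
#' @export
gibbs_helmholtz_mu <- function(mu0, t0, h_table, temperature,
                               max_step = 0.001) {
  stopifnot(t0 > 0, all(temperature > 0))
  if (is.null(h_table) || nrow(h_table) == 0) stop("empty enthalpy table")
  beta0 <- 1 / t0
  hb <- data.frame(beta = 1 / h_table$T, h = h_table$h)
  vapply(temperature, function(tt) {
    beta1 <- 1 / tt
    if (beta1 == beta0) return(mu0)
    k <- max(2L, ceiling(abs(beta1 - beta0) / max_step) + 1L)
    bg <- seq(beta0, beta1, length.out = k)
    h <- .interp_extrap(hb$beta, hb$h, bg)
    integral <- sum(diff(bg) * (h[-1] + h[-length(h)]) / 2)
    (beta0 * mu0 + integral) / beta1
  }, numeric(1))
}

# bisection to |dT| < tol; f must change sign on [lo, hi]
.bisect <- function(f, lo, hi, tol = 1e-6) {
  flo <- f(lo)
  fhi <- f(hi)
  if (flo == 0) return(lo)
  if (fhi == 0) return(hi)
  if (flo * fhi > 0)
    stop("no sign change in the search bracket: cannot locate the root")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (fm == 0) return(mid)
    if (flo * fm < 0) {
      hi <- mid
    } else {
      lo <- mid
      flo <- fm
    }
  }
  (lo + hi) / 2
}

#' Melting point from liquid and solid chemical potentials
#'
#' Finds the temperature at which the two bulk chemical potentials are
#' equal, propagating both from a common reference temperature with
#' [gibbs_helmholtz_mu()] and bisecting `Delta(beta mu)(T) = 0` to
#' `|dT| < tol`. Uncertainty is estimated by resampling the reference
#' chemical potentials (and, when an `h_se` column is present, the
#' enthalpy tables) from their stated errors.
#'
#' @param mu_liq,mu_sol Reference chemical potentials at `t0`.
#' @param t0 Reference temperature.
#' @param h_liq,h_sol Enthalpy tables (see [gibbs_helmholtz_mu()]).
#' @param pressure Pressure of the common isobar (carried into the result).
#' @param bracket Search bracket in temperature.
#' @param tol Bisection tolerance.
#' @param mu_liq_se,mu_sol_se Errors of the reference chemical potentials.
#' @param n_draws Resampling draws (0 disables; >= 1000 recommended when
#'   errors are supplied).
#' @param seed Seed for the resampling.
#' @return A [phase_point()] labelled `"melting"`.
#' @export
melting_point <- function(mu_liq, mu_sol, t0, h_liq, h_sol,
                          pressure = NA_real_, bracket = c(0.5, 0.95),
                          tol = 1e-6, mu_liq_se = 0, mu_sol_se = 0,
                          n_draws = 0, seed = 1) {
  solve_tm <- function(ml, ms, hl, hs) {
    if (ml == ms) return(t0)
    f <- function(tt)
      (gibbs_helmholtz_mu(ms, t0, hs, tt) -
         gibbs_helmholtz_mu(ml, t0, hl, tt)) / tt
    .bisect(f, bracket[1], bracket[2], tol)
  }
  tm <- solve_tm(mu_liq, mu_sol, h_liq, h_sol)
  t_se <- 0
  if (n_draws > 0) {
    rng <- new_rng(seed)
    draws <- vapply(seq_len(n_draws), function(q) {
      hl <- h_liq
      hs <- h_sol
      if (!is.null(h_liq$h_se)) hl$h <- hl$h + rng$norm(nrow(hl)) * hl$h_se
      if (!is.null(h_sol$h_se)) hs$h <- hs$h + rng$norm(nrow(hs)) * hs$h_se
      tryCatch(solve_tm(mu_liq + rng$norm(1) * mu_liq_se,
                        mu_sol + rng$norm(1) * mu_sol_se, hl, hs),
               error = function(e) NA_real_)
    }, numeric(1))
    t_se <- sd(draws, na.rm = TRUE)
  }
  phase_point(tm, pressure, "melting", t_se = t_se)
}

#' Trace the solid-liquid coexistence line (Clapeyron)
#'
#' Integrates `dP/dT = Delta h / (T Delta v)` from a starting coexistence
#' point with classical 4th-order Runge-Kutta at step `<= step`.
#' `delta_h` and `delta_v` (per-particle differences liquid minus solid,
#' or any consistent convention) may be constants or functions of
#' `(T, P)`.
#'
#' @param start A [phase_point()] with finite pressure.
#' @param delta_h,delta_v Constants or `function(T, P)`.
#' @param t_end End temperature.
#' @param step Maximum integration step in temperature.
#' @return A [coexistence_curve()] labelled `"SL"`.
#' @export
clapeyron_curve <- function(start, delta_h, delta_v, t_end, step = 5e-4) {
  stopifnot(is.finite(start$pressure))
  dh <- if (is.function(delta_h)) delta_h else function(tt, pp) delta_h
  dv <- if (is.function(delta_v)) delta_v else function(tt, pp) delta_v
  rhs <- function(tt, pp) {
    v <- dv(tt, pp)
    if (abs(v) < 1e-12)
      stop("volume difference vanished along the coexistence line")
    dh(tt, pp) / (tt * v)
  }
  t0 <- start$temperature
  n_steps <- max(1L, ceiling(abs(t_end - t0) / step))
  hstep <- (t_end - t0) / n_steps
  tt <- numeric(n_steps + 1)
  pp <- numeric(n_steps + 1)
  tt[1] <- t0
  pp[1] <- start$pressure
  for (q in seq_len(n_steps)) {
    k1 <- rhs(tt[q], pp[q])
    k2 <- rhs(tt[q] + hstep / 2, pp[q] + hstep * k1 / 2)
    k3 <- rhs(tt[q] + hstep / 2, pp[q] + hstep * k2 / 2)
    k4 <- rhs(tt[q] + hstep, pp[q] + hstep * k3)
    pp[q + 1] <- pp[q] + hstep * (k1 + 2 * k2 + 2 * k3 + k4) / 6
    tt[q + 1] <- t0 + q * hstep
  }
  ord <- order(tt)
  coexistence_curve(tt[ord], pp[ord], "SL")
}

#' Locate the triple point
#'
#' Intersects the solid-liquid and liquid-vapor coexistence curves by
#' monotone interpolation and root bracketing over their temperature
#' overlap. Optional pressure-shift errors on either curve propagate into
#' the result by resampling.
#'
#' @param sl,lv [coexistence_curve()] objects (SL and LV).
#' @param sl_p_se,lv_p_se Optional common pressure-shift errors.
#' @param n_draws Resampling draws (0 disables).
#' @param seed Seed for the resampling.
#' @return A [phase_point()] labelled `"triple"`.
#' @export
triple_point <- function(sl, lv, sl_p_se = 0, lv_p_se = 0, n_draws = 0,
                         seed = 1) {
  lo <- max(min(sl$T), min(lv$T))
  hi <- min(max(sl$T), max(lv$T))
  if (lo >= hi) stop("curves do not overlap in temperature")
  locate <- function(d_sl, d_lv) {
    f_sl <- stats::approxfun(sl$T, sl$P + d_sl)
    f_lv <- stats::approxfun(lv$T, lv$P + d_lv)
    g <- function(tt) f_sl(tt) - f_lv(tt)
    grid <- seq(lo, hi, length.out = 257)
    gv <- g(grid)
    if (all(abs(gv) < 1e-14))
      stop("degenerate input: the curves coincide")
    sgn <- sign(gv)
    cross <- which(sgn[-1] * sgn[-length(sgn)] <= 0)
    if (!length(cross)) stop("curves do not cross in the overlap region")
    q <- cross[1]
    tt <- .bisect(g, grid[q], grid[q + 1], tol = 1e-9)
    c(tt, f_lv(tt))
  }
  base <- locate(0, 0)
  t_se <- p_se <- 0
  if (n_draws > 0 && (sl_p_se > 0 || lv_p_se > 0)) {
    rng <- new_rng(seed)
    draws <- vapply(seq_len(n_draws), function(q)
      tryCatch(locate(rng$norm(1) * sl_p_se, rng$norm(1) * lv_p_se),
               error = function(e) c(NA_real_, NA_real_)),
      numeric(2))
    t_se <- sd(draws[1, ], na.rm = TRUE)
    p_se <- sd(draws[2, ], na.rm = TRUE)
  }
  phase_point(base[1], base[2], "triple", t_se = t_se, p_se = p_se)
}

# small local RNG so resampling does not disturb the global .Random.seed
new_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, globalenv())
    s
  })
  list(norm = function(n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    out <- rnorm(n)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, globalenv())
    out
  })
}
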