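test_that("Gibbs-Helmholtz propagation matches closed forms", {
  # h = 0: beta*mu constant, mu scales with T
  h0 <- data.frame(T = c(0.5, 0.9), h = c(0, 0))
  expect_equal(gibbs_helmholtz_mu(-4, 0.6, h0, 0.75), -4 * 0.75 / 0.6,
               tolerance = 1e-12)
  # T = T0 returns mu0 exactly
  expect_equal(gibbs_helmholtz_mu(-4, 0.6, h0, 0.6), -4)
  # constant h: beta mu(T) = beta0 mu0 + h (beta - beta0)
  hc <- data.frame(T = c(0.5, 0.9), h = c(-6.2, -6.2))
  for (tt in c(0.55, 0.62, 0.8)) {
    exact <- (-4.5 / 0.6 - 6.2 * (1 / tt - 1 / 0.6)) * tt
    expect_equal(gibbs_helmholtz_mu(-4.5, 0.6, hc, tt), exact,
                 tolerance = 1e-10)
  }
  expect_error(gibbs_helmholtz_mu(-4, 0.6, data.frame(), 0.7), "empty")
})

test_that("Gibbs-Helmholtz integration is reversible", {
  h <- data.frame(T = seq(0.5, 0.9, by = 0.1),
                  h = c(-6.9, -6.5, -6.2, -6.0, -5.7))
  mu1 <- gibbs_helmholtz_mu(-4.3, 0.6, h, 0.82)
  back <- gibbs_helmholtz_mu(mu1, 0.82, h, 0.6)
  expect_equal(back, -4.3, tolerance = 1e-9)
})

test_that("melting point solves the constant-enthalpy closed form", {
  # equal chemical potentials: T_m = T0
  hl <- data.frame(T = c(0.5, 0.9), h = c(-6, -6))
  hs <- data.frame(T = c(0.5, 0.9), h = c(-7, -7))
  expect_equal(melting_point(-4.5, -4.5, 0.6, hl, hs)$temperature, 0.6)

  # constant dh: beta0 dmu0 + dh (beta - beta0) = 0 analytically
  dmu0 <- -0.14
  dh <- -1.0  # h_sol - h_liq from the tables above
  beta_m <- 1 / 0.6 - (dmu0 / 0.6) / dh
  pt <- melting_point(-4.6594, -4.6594 + dmu0, 0.6, hl, hs,
                      bracket = c(0.55, 0.9), tol = 1e-8)
  expect_equal(pt$temperature, 1 / beta_m, tolerance = 1e-6)

  # invariance under a common shift of both chemical potentials
  pt2 <- melting_point(-4.6594 + 2, -4.6594 + dmu0 + 2, 0.6, hl, hs,
                       bracket = c(0.55, 0.9), tol = 1e-8)
  expect_equal(pt2$temperature, pt$temperature, tolerance = 1e-6)

  expect_error(melting_point(-4.0, -5.5, 0.6, hl, hs,
                             bracket = c(0.58, 0.62)), "sign change")

  # resampling produces a finite uncertainty
  ptu <- melting_point(-4.6594, -4.6594 + dmu0, 0.6, hl, hs,
                       mu_liq_se = 0.001, mu_sol_se = 0.001,
                       n_draws = 200, seed = 2)
  expect_gt(ptu$t_se, 0)
})

test_that("Clapeyron tracing matches the constant-coefficient solution", {
  start <- phase_point(0.69, 0.001, "melting")
  # dh = 0: pressure stays constant
  flat <- clapeyron_curve(start, 0, 0.15, 0.72)
  expect_equal(unique(round(flat$P, 15)), 0.001)
  # constants: P(T) = P0 + (dh/dv) ln(T/T0)
  cur <- clapeyron_curve(start, 1.1, 0.15, 0.73, step = 5e-4)
  exact <- 0.001 + (1.1 / 0.15) * log(cur$T / 0.69)
  expect_lt(max(abs(cur$P - exact)), 1e-8)
  # halving the step barely moves the endpoint (4th-order accuracy)
  cur2 <- clapeyron_curve(start, 1.1, 0.15, 0.73, step = 2.5e-4)
  expect_lt(abs(cur2$P[nrow(cur2)] - cur$P[nrow(cur)]), 1e-6)
  expect_error(clapeyron_curve(start, 1.1, 0, 0.73), "vanished")
})

test_that("triple point recovers a constructed intersection exactly", {
  tgrid <- seq(0.6, 0.8, by = 0.01)
  sl <- coexistence_curve(tgrid, 0.005 + 10 * (tgrid - 0.69), "SL")
  lv <- coexistence_curve(tgrid, 0.005 + 0.02 * (tgrid - 0.69), "LV")
  tp <- triple_point(sl, lv)
  expect_equal(tp$temperature, 0.69, tolerance = 1e-7)
  expect_equal(tp$pressure, 0.005, tolerance = 1e-7)
  expect_error(triple_point(sl, sl), "coincide")
  shifted <- coexistence_curve(tgrid, sl$P + 1, "LV")
  expect_error(triple_point(sl, shifted), "cross")
})

test_that("simulated enthalpies put the melting and triple points near 0.69", {
  # short NPT runs at three temperatures per phase (reduced-size systems;
  # reference chemical potentials at T0 = 0.6 from the cluster analysis)
  temps <- c(0.60, 0.66, 0.72)
  sim <- function(phase, tt, seed) {
    run_npt(phase, 256, temperature = tt,
            pressure = lj_saturation_pressure(0.6), cutoff = 3.0,
            sweeps = 1200, equil = 500, seed = seed)
  }
  liq <- lapply(seq_along(temps), function(q) sim("liquid", temps[q], q))
  sol <- lapply(seq_along(temps), function(q) sim("fcc_solid", temps[q],
                                                  10 + q))
  h_liq <- data.frame(T = temps, h = vapply(liq, `[[`, 0, "h"),
                      h_se = vapply(liq, `[[`, 0, "h_se"))
  h_sol <- data.frame(T = temps, h = vapply(sol, `[[`, 0, "h"),
                      h_se = vapply(sol, `[[`, 0, "h_se"))
  pt <- melting_point(-4.6594, -4.7990, 0.6, h_liq, h_sol,
                      pressure = lj_saturation_pressure(0.6),
                      bracket = c(0.6, 0.85), mu_liq_se = 0.0009,
                      mu_sol_se = 0.0006, n_draws = 300, seed = 3)
  expect_gt(pt$temperature, 0.64)
  expect_lt(pt$temperature, 0.75)

  # Clapeyron line upward from the melting point, crossed with the
  # packaged liquid-vapor curve: the triple point sits just above T_m
  dh <- approx(h_liq$T, h_liq$h, pt$temperature, rule = 2)$y -
    approx(h_sol$T, h_sol$h, pt$temperature, rule = 2)$y
  rho_l <- approx(temps, vapply(liq, `[[`, 0, "rho"), pt$temperature,
                  rule = 2)$y
  rho_s <- approx(temps, vapply(sol, `[[`, 0, "rho"), pt$temperature,
                  rule = 2)$y
  dv <- 1 / rho_l - 1 / rho_s
  sl <- clapeyron_curve(pt, dh, dv, pt$temperature + 0.02)
  lv <- read_coexistence_curve(
    system.file("extdata", "lj_lv_coexistence_synthetic.tsv",
                package = "avbmclj"))
  tp <- triple_point(sl, lv)
  expect_gte(tp$temperature, pt$temperature)
  expect_lt(tp$temperature - pt$temperature, 0.005)
})
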