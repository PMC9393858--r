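test_that("unbias recovers flat and stepped histograms exactly", {
  h <- size_histogram(5:10, matrix(100, 6, 5))
  prof <- unbias(h, NULL, temperature = 1)
  expect_equal(prof$delta_G, rep(0, 6))
  expect_equal(prof$se, rep(0, 6))

  # H(n)/H(n-1) = e^-1 at zero bias and T = 1 gives delta-dG = +1
  counts <- matrix(rep(1000 * exp(-(0:4)), 5), ncol = 5)
  h2 <- size_histogram(1:5, counts)
  s <- delta_g_series(unbias(h2, NULL, temperature = 1))
  expect_equal(s$ddg, rep(1, 4), tolerance = 1e-12)

  # unvisited size is a hard error naming the size
  counts[3, 2] <- 0
  expect_error(unbias(size_histogram(1:5, counts), NULL, 1),
               "insufficient sampling.*3")
})

test_that("synthetic sampler round-trips a known profile through a bias", {
  n <- 1:12
  g_true <- 0.3 * n + 1.5 * sin(n / 2)
  g_true <- g_true - g_true[1]
  eta <- -g_true + runif(12, -0.3, 0.3)
  h <- synthetic_size_histogram(n, g_true, eta, temperature = 0.7,
                                draws = 40000, seed = 4)
  prof <- unbias(h, bias_potential(n, eta), temperature = 0.7,
                 anchor = c(1, 0))
  err <- abs(prof$delta_G - g_true)
  expect_true(all(err[-1] < 3 * prof$se[-1] + 0.02))
})

test_that("delta-dG series is exactly anchor independent", {
  n <- 1:10
  g <- cumsum(c(0, runif(9, -2, 1)))
  h <- synthetic_size_histogram(n, g, -g, temperature = 1, draws = 20000,
                                seed = 8)
  p1 <- unbias(h, bias_potential(n, -g), 1, anchor = c(1, 0))
  p2 <- unbias(h, bias_potential(n, -g), 1, anchor = c(5, 7))
  s1 <- delta_g_series(p1)
  s2 <- delta_g_series(p2)
  expect_equal(s1$ddg, s2$ddg, tolerance = 1e-12)
  expect_equal(s1$se, s2$se, tolerance = 1e-12)
  # shifting a whole profile leaves the series unchanged
  p3 <- p1
  p3$delta_G <- p3$delta_G + 7
  expect_equal(delta_g_series(p3)$ddg, s1$ddg, tolerance = 1e-12)
})

test_that("bias adaptation flattens a two-state toy in one iteration", {
  # perfectly flat profile adapts to a constant bias
  flat <- data.frame(n = 1:5, delta_G = rep(2, 5), se = 0)
  class(flat) <- c("free_energy_profile", "data.frame")
  expect_equal(diff(adapt_bias(flat)$eta), rep(0, 4))

  # two-state toy with a 5 kT gap
  n <- 1:2
  g <- c(0, 5)
  h0 <- synthetic_size_histogram(n, g, c(0, 0), temperature = 1,
                                 draws = 50000, seed = 2)
  expect_gt(even_sampling_ratio(h0), 50)
  prof <- unbias(h0, NULL, 1)
  b1 <- adapt_bias(prof)
  h1 <- synthetic_size_histogram(n, g, bias_value(b1, n), temperature = 1,
                                 draws = 50000, seed = 3)
  expect_lt(even_sampling_ratio(h1), 2)

  # idempotence: adapting from the exact profile gives even sampling
  exact <- data.frame(n = n, delta_G = g, se = 0)
  class(exact) <- c("free_energy_profile", "data.frame")
  h2 <- synthetic_size_histogram(n, g, bias_value(adapt_bias(exact), n),
                                 temperature = 1, draws = 50000, seed = 5)
  expect_lt(even_sampling_ratio(h2), 1.1)
})

test_that("adaptation extrapolates the bias across unvisited sizes", {
  prof <- data.frame(n = 6:10, delta_G = -2 * (6:10), se = 0)
  class(prof) <- c("free_energy_profile", "data.frame")
  b <- adapt_bias(prof, size_window(1, 14))
  expect_equal(b$n, 1:14)
  expect_equal(diff(b$eta), rep(2, 13), tolerance = 1e-12)
})

test_that("CNT bias extension reproduces an exact CNT profile", {
  b <- -4.5
  s <- 6.2
  n <- 2:60
  x <- n^(2 / 3) - (n - 1)^(2 / 3)
  g <- cumsum(b + s * x)  # dG relative to dG(1) = 0
  fit <- fit_delta_g(data.frame(n = n, x = x, ddg = b + s * x, se = 0.001),
                     range = c(2, 50))
  ext <- cnt_extend_bias(fit, n_ref = 50, g_ref = g[n == 50],
                         n_target = 100)
  g100 <- sum(b + s * ((2:100)^(2 / 3) - (1:99)^(2 / 3)))
  expect_equal(bias_value(ext, 100), -g100, tolerance = 1e-9)

  # degenerate slopes
  z <- cnt_fit(slope = 0, intercept = 0)
  expect_equal(unique(cnt_extend_bias(z, 5, 1.5, 20)$eta), -1.5)
  m <- cnt_fit(slope = 0, intercept = -1)
  expect_equal(diff(cnt_extend_bias(m, 5, 0, 20)$eta), rep(1, 15))
  expect_error(cnt_extend_bias(z, 10, 0, 5), "below")
})

test_that("block errors shrink like one over sqrt of samples", {
  n <- 1:8
  g <- 0.4 * n
  se_at <- function(draws, seed) {
    h <- synthetic_size_histogram(n, g, -g, 1, draws = draws, seed = seed)
    mean(delta_g_series(unbias(h, bias_potential(n, -g), 1))$se)
  }
  r <- mean(vapply(1:6, function(q) se_at(4000, q) / se_at(16000, q + 50),
                   numeric(1)))
  expect_gt(r, 1.4)
  expect_lt(r, 2.6)
})

test_that("delta-dG does not depend on the bias used", {
  # same tiny frozen-energy solid model sampled under two different biases
  tm <- three_site_model()
  res <- reservoir_spec(0.6, 1)
  mp <- move_params(0.4)
  tab <- avbmclj:::.site_tables(tm$lattice, sites = tm$sites)
  st <- cluster_state(tab$pos[1, , drop = FALSE], "solid",
                      lattice = tm$lattice, site_ids = tm$sites$id[1])
  eng <- list(site_pos = tab$pos, site_nbr = tab$nbr, occ0 = 0L,
              sites = tm$sites)
  win <- size_window(1, 3)
  series_under <- function(bias, seed) {
    run <- run_gc_cluster(st, res, mp, win, bias = bias, n_moves = 4e5,
                          seed = seed, energy_mode = "frozen",
                          sample_every = 20, .engine = eng)
    delta_g_series(unbias(run$histogram, bias, res$temperature))
  }
  s1 <- series_under(NULL, 11)
  s2 <- series_under(bias_potential(1:3, c(0, -1.2, -2.0)), 12)
  comb <- sqrt(s1$se^2 + s2$se^2)
  expect_true(all(abs(s1$ddg - s2$ddg) < 3 * comb))
})

test_that("profiles stitch by least-squares alignment on the overlap", {
  p1 <- data.frame(n = 1:6, delta_G = 0.5 * (1:6), se = 0.01)
  class(p1) <- c("free_energy_profile", "data.frame")
  p2 <- data.frame(n = 5:10, delta_G = 0.5 * (5:10) + 3.3, se = 0.01)
  class(p2) <- c("free_energy_profile", "data.frame")
  st <- stitch_profiles(p1, p2)
  expect_equal(st$delta_G, 0.5 * (1:10), tolerance = 1e-10)
  expect_error(stitch_profiles(p1[1:2, ], p2), "overlap")
})
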