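res06 <- reservoir_spec(0.6, 1)

test_that("identical seeds give bit-identical runs", {
  lat <- fcc_lattice(1.128)
  st <- initial_solid_cluster(13, lat)
  mp <- move_params(0.5)
  win <- size_window(10, 16)
  a <- run_gc_cluster(st, res06, mp, win, n_moves = 20000, seed = 42)
  b <- run_gc_cluster(st, res06, mp, win, n_moves = 20000, seed = 42)
  expect_identical(a$histogram$counts, b$histogram$counts)
  expect_identical(a$state$config$positions, b$state$config$positions)
  c <- run_gc_cluster(st, res06, mp, win, n_moves = 20000, seed = 43)
  expect_false(identical(a$histogram$counts, c$histogram$counts))
})

test_that("forward/reverse acceptance arguments multiply to one", {
  # along the same path, with the energy change reversing sign, detailed
  # balance demands arg_insert(pre) * arg_delete(post) == 1
  for (case in 1:20) {
    set.seed(case)
    N <- sample(2:40, 1)
    N_in <- sample(0:11, 1)
    N_vac <- sample(1:(12 - N_in), 1)
    dE <- rnorm(1)
    beta <- runif(1, 0.5, 3)
    z_args <- list(beta = beta, n_v = runif(1, 0.1, 2),
                   v_in = runif(1, 0.1, 2))
    f <- do.call(acceptance_argument,
                 c(list("insert", "lattice", N = N, N_in = N_in,
                        N_vac = N_vac, delta_E = dE), z_args))
    r <- do.call(acceptance_argument,
                 c(list("delete", "lattice", N = N + 1, N_in = N_in + 1,
                        N_vac = N_vac - 1, delta_E = -dE), z_args))
    expect_equal(f * r, 1, tolerance = 1e-12)
    fo <- do.call(acceptance_argument,
                  c(list("insert", "original", N = N, N_in = N_in,
                         delta_E = dE), z_args))
    ro <- do.call(acceptance_argument,
                  c(list("delete", "original", N = N + 1, N_in = N_in + 1,
                         delta_E = -dE), z_args))
    expect_equal(fo * ro, 1, tolerance = 1e-12)
  }
})

test_that("ideal-gas dimer matches the mass-action ratio", {
  # For an ideal gas the stationary dimer/monomer ratio is the law of mass
  # action with the pair symmetry factor: c2/c1 = n_v V_in / 2 (two
  # monomer 'patterns' merge into one dimer, exactly as in the two-site
  # lattice enumeration).
  res <- reservoir_spec(0.6, 0.05)
  mp <- move_params(1.5)
  st <- cluster_state(matrix(0, 1, 3), "liquid")
  out <- run_gc_cluster(st, res, mp, size_window(1, 2), n_moves = 3e5,
                        seed = 3, energy_mode = "ideal", sample_every = 10)
  rat <- out$histogram$counts[2, ] / out$histogram$counts[1, ]
  se <- sd(rat) / sqrt(length(rat))
  expected <- 0.05 * mp$v_in / 2
  expect_lt(abs(mean(rat) - expected), 3 * se + 1e-12)
})

test_that("single-move operations report proposals and honor auto-rejects", {
  lat <- fcc_lattice(1.128)
  st <- initial_solid_cluster(13, lat)
  mp <- move_params(0.5)

  # window pinned at the current size: every swap proposal is auto-rejected
  # and the state must come back bit-identical
  for (q in 1:25) {
    out <- lattice_avbmc_swap(st, res06, mp, size_window(13, 13),
                              seed = 100 + q)
    expect_false(out$proposal$accepted)
    expect_identical(out$state$config$positions, st$config$positions)
    expect_identical(out$state$site_ids, st$site_ids)
  }

  # deletion from a monomer is auto-rejected (no neighbors, N = n_min)
  mono <- cluster_state(matrix(0, 1, 3), "solid", lattice = lat,
                        site_ids = 0)
  out <- lattice_avbmc_swap(mono, res06, mp, size_window(1, 2), seed = 7)
  expect_s3_class(out$state, "cluster_state")

  liq <- cluster_state(rbind(c(0, 0, 0), c(1.2, 0, 0)), "liquid")
  outl <- original_avbmc_swap(liq, res06, move_params(1.5),
                              size_window(2, 2), seed = 5)
  expect_false(outl$proposal$accepted)
  expect_identical(outl$state$config$positions, liq$config$positions)
})

test_that("ideal intrasite jumps always accept and fill the sphere uniformly", {
  lat <- fcc_lattice(1.128)
  mono <- cluster_state(matrix(0, 1, 3), "solid", lattice = lat,
                        site_ids = 0)
  mp <- move_params(0.5)
  out <- run_gc_cluster(mono, res06, mp, size_window(1, 1),
                        n_moves = 4000, seed = 9, p_swap = 0,
                        energy_mode = "ideal", traj_every = 2)
  expect_equal(out$stats$rate[out$stats$move == "intrasite"], 1)
  d <- vapply(out$trajectory, function(x) sqrt(sum(x[1, ]^2)), numeric(1))
  # uniform in the sphere: d^3/r^3 is uniform on (0,1); chi-square over
  # 10 equal-volume radial shells
  shells <- findInterval((d / 0.5)^3, seq(0, 1, by = 0.1),
                         rightmost.closed = TRUE)
  p <- stats::chisq.test(tabulate(shells, 10))$p.value
  expect_gt(p, 0.01)
})

test_that("translations respect the displacement cap and pair Boltzmann", {
  res <- reservoir_spec(0.6, 1)
  mp <- move_params(1.5, max_displacement = 0.2)
  mono <- cluster_state(matrix(0, 1, 3), "liquid")
  out <- run_gc_cluster(mono, res, mp, size_window(1, 1), n_moves = 300,
                        seed = 17, p_swap = 0, energy_mode = "ideal",
                        traj_every = 1)
  expect_equal(out$stats$rate[out$stats$move == "translate"], 1)
  steps <- do.call(rbind, lapply(seq_along(out$trajectory)[-1], function(q)
    out$trajectory[[q]] - out$trajectory[[q - 1]]))
  expect_lt(max(abs(steps)), 0.2 + 1e-12)

  # two-particle cluster: pair-distance density ~ r^2 exp(-beta u(r)) on
  # (0, R); compared against 1D quadrature
  dimer <- cluster_state(rbind(c(0, 0, 0), c(1.1, 0, 0)), "liquid")
  run <- run_gc_cluster(dimer, res, mp, size_window(2, 2), n_moves = 2e5,
                        seed = 23, p_swap = 0, traj_every = 40)
  d <- vapply(run$trajectory, function(x) sqrt(sum((x[1, ] - x[2, ])^2)),
              numeric(1))
  expect_true(all(d < 1.5))
  breaks <- c(seq(0.95, 1.35, by = 0.05), 1.5)
  dens <- function(r) r^2 * exp(-pair_energy(r) / 0.6)
  probs <- vapply(seq_len(length(breaks) - 1), function(q)
    stats::integrate(dens, breaks[q], breaks[q + 1])$value, numeric(1))
  probs_all <- c(stats::integrate(dens, 1e-6, breaks[1])$value, probs)
  probs_all <- probs_all / sum(probs_all)
  counts <- tabulate(findInterval(d, c(0, breaks),
                                  rightmost.closed = TRUE),
                     nbins = length(probs_all))
  p <- stats::chisq.test(counts, p = probs_all, rescale.p = TRUE)$p.value
  expect_gt(p, 0.01)
})

test_that("histogram support stays inside the window and audits pass", {
  lat <- fcc_lattice(1.128)
  st <- initial_solid_cluster(12, lat)
  out <- run_gc_cluster(st, res06, move_params(0.5), size_window(10, 14),
                        n_moves = 5e4, seed = 4)
  visited <- out$histogram$n[rowSums(out$histogram$counts) > 0]
  expect_true(all(visited >= 10 & visited <= 14))
  expect_true(out$audit$occupancy_ok)
  expect_lt(abs(out$audit$energy_drift), 1e-7)
  expect_equal(sum(out$histogram$counts), 5e4)
})

test_that("zero moves produce an empty histogram", {
  mono <- cluster_state(matrix(0, 1, 3), "liquid")
  out <- run_gc_cluster(mono, reservoir_spec(1, 1), move_params(1.5),
                        size_window(1, 2), n_moves = 0, seed = 1)
  expect_equal(sum(out$histogram$counts), 0)
})

test_that("swap acceptance decreases with cluster size", {
  lat <- fcc_lattice(1.128)
  mp <- move_params(0.5)
  rate_at <- function(n0, seed) {
    st <- initial_solid_cluster(n0, lat)
    warm <- run_gc_cluster(st, res06, mp, size_window(n0, n0),
                           n_moves = 3e4, seed = seed, p_swap = 0)
    out <- run_gc_cluster(warm$state, res06, mp,
                          size_window(n0 - 2, n0 + 2), n_moves = 1e5,
                          seed = seed + 1)
    sw <- out$stats[out$stats$move %in% c("insert", "delete"), ]
    sum(sw$accepts) / sum(sw$attempts)
  }
  r_small <- rate_at(30, 50)
  r_large <- rate_at(150, 60)
  expect_gt(r_small, r_large)
})
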