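test_that("pair energy reproduces the 12-6 form at landmark distances", {
  expect_equal(pair_energy(2^(1 / 6)), -1)
  expect_equal(pair_energy(1), 0)
  expect_equal(pair_energy(2), 4 * (2^-12 - 2^-6))
  # cutoff truncation
  spec <- lj_spec(cutoff = 2.5)
  expect_equal(pair_energy(3, spec), 0)
  expect_equal(pair_energy(2, spec), pair_energy(2))
  expect_error(pair_energy(0), "positive")
  # scaling in epsilon and sigma
  expect_equal(pair_energy(2^(1 / 6) * 1.7, lj_spec(epsilon = 3, sigma = 1.7)),
               -3)
})

test_that("total energy equals the brute-force pair sum", {
  empty <- particle_config(matrix(numeric(0), 0, 3))
  expect_equal(total_energy(empty), 0)
  one <- particle_config(matrix(0, 1, 3))
  expect_equal(total_energy(one), 0)
  dimer <- particle_config(rbind(c(0, 0, 0), c(2^(1 / 6), 0, 0)))
  expect_equal(total_energy(dimer), -1)

  pos13 <- fcc13(1.128)
  expect_equal(total_energy(particle_config(pos13)), brute_energy(pos13),
               tolerance = 1e-12)

  set.seed(42)
  pos <- matrix(runif(60, 0, 4), ncol = 3)
  expect_equal(total_energy(particle_config(pos)), brute_energy(pos),
               tolerance = 1e-12)

  # bulk: minimum image against brute force
  box <- 6
  spec <- lj_spec(cutoff = 2.5)
  posb <- matrix(runif(90, 0, box), ncol = 3)
  expect_equal(total_energy(particle_config(posb, box, "bulk"), spec),
               brute_energy(posb, cutoff = 2.5, box = box),
               tolerance = 1e-12)

  expect_error(total_energy(particle_config(rbind(c(0, 0, 0), c(0, 0, 0)))),
               "overlap")
})

test_that("incremental move energies match a full recompute", {
  dimer <- particle_config(rbind(c(0, 0, 0), c(2^(1 / 6), 0, 0)))
  expect_equal(delta_energy(dimer, "deletion", index = 2), 1)
  expect_lt(abs(delta_energy(dimer, "insertion", position = c(1e5, 0, 0))),
            1e-25)
  expect_error(delta_energy(dimer, "deletion", index = 7), "out of range")

  set.seed(7)
  for (n in c(5, 12, 20)) {
    pos <- matrix(rnorm(3 * n, sd = n^(1 / 3)), ncol = 3)
    config <- particle_config(pos)
    e0 <- total_energy(config)
    for (rep in 1:40) {
      kind <- sample(c("insertion", "deletion", "displacement"), 1)
      if (kind == "insertion") {
        p <- rnorm(3, sd = n^(1 / 3))
        de <- delta_energy(config, "insertion", position = p)
        e1 <- total_energy(particle_config(rbind(pos, p)))
      } else if (kind == "deletion") {
        k <- sample(n, 1)
        de <- delta_energy(config, "deletion", index = k)
        e1 <- total_energy(particle_config(pos[-k, , drop = FALSE]))
      } else {
        k <- sample(n, 1)
        p <- pos[k, ] + rnorm(3, sd = 0.1)
        de <- delta_energy(config, "displacement", index = k, position = p)
        pos2 <- pos
        pos2[k, ] <- p
        e1 <- total_energy(particle_config(pos2))
      }
      # agreement relative to the energy scale of the system
      expect_lt(abs(de - (e1 - e0)), 1e-9 * max(1, abs(e0)))
    }
  }
})

test_that("tail corrections match numerical quadrature", {
  expect_equal(unlist(tail_correction(0, 4.75)), c(energy = 0, pressure = 0))
  far <- tail_correction(0.8, 1e4)
  expect_lt(abs(far$energy), 1e-10)
  expect_lt(abs(far$pressure), 1e-10)

  rho <- 0.8
  rc <- 4.75
  u_quad <- stats::integrate(function(r)
    4 * (r^-12 - r^-6) * rho * 4 * pi * r^2 / 2, rc, Inf,
    rel.tol = 1e-12)$value
  expect_equal(tail_correction(rho, rc)$energy, u_quad, tolerance = 1e-9)
  # pressure correction: -(1/3) rho^2/2 * int r du/dr 4 pi r^2 dr
  p_quad <- -stats::integrate(function(r)
    -48 * (r^-12 - 0.5 * r^-6) * r^2, rc, Inf,
    rel.tol = 1e-12)$value * 4 * pi * rho^2 / 6
  expect_equal(tail_correction(rho, rc)$pressure, p_quad, tolerance = 1e-9)
})

test_that("cluster energies are translation and rotation invariant", {
  set.seed(11)
  pos <- matrix(rnorm(45, sd = 1.5), ncol = 3)
  e0 <- total_energy(particle_config(pos))
  shifted <- sweep(pos, 2, c(11.3, -2.7, 0.4), "+")
  expect_equal(total_energy(particle_config(shifted)), e0,
               tolerance = 1e-12)
  rot <- random_rotation(3)
  expect_equal(total_energy(particle_config(pos %*% rot)), e0,
               tolerance = 1e-10)
})

test_that("bulk energy per particle stabilizes as the cutoff grows", {
  set.seed(5)
  config <- fcc_box_config(256, 0.8)
  jig <- config$positions + matrix(rnorm(768, sd = 0.05), ncol = 3)
  config <- particle_config(jig, config$box_length, "bulk")
  u <- vapply(c(2.0, 2.6, 3.2), function(rc)
    total_energy(config, lj_spec(cutoff = rc, tail_corrections = TRUE)) / 256,
    numeric(1))
  # with tail corrections the truncated energies converge toward each
  # other as the cutoff grows (residual: g(r) structure beyond the cutoff)
  expect_lt(abs(u[3] - u[2]), abs(u[2] - u[1]))
  expect_lt(abs(u[3] - u[2]), 0.01)
})

test_that("XYZ files round-trip both modes", {
  path <- withr::local_tempfile(fileext = ".xyz")
  pos <- matrix(c(0.123456789, 1, 2, 3, 4, 5), ncol = 3, byrow = TRUE)
  write_xyz(particle_config(pos), path)
  back <- read_xyz(path)
  expect_equal(back$mode, "cluster")
  expect_equal(back$positions, pos, tolerance = 1e-9)

  write_xyz(particle_config(pos, 10, "bulk"), path)
  backb <- read_xyz(path)
  expect_equal(backb$mode, "bulk")
  expect_equal(backb$box_length, 10)
  expect_equal(backb$positions, pos, tolerance = 1e-9)
})
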