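test_that("site generation is deterministic with stable ids", {
  lat <- fcc_lattice(1.128)
  small <- generate_sites(lat, 1.2)
  expect_equal(nrow(small), 13)  # origin + 12 nearest neighbors
  # conventional cubic cell edge a = spacing * sqrt(2)
  expect_equal(max(abs(small$x)), 1.128 * sqrt(2) / 2, tolerance = 1e-12)

  big <- generate_sites(lat, 3.0)
  idx <- match(small$id, big$id)
  expect_false(anyNA(idx))
  expect_identical(small$x, big$x[idx])
  expect_identical(small$y, big$y[idx])
  expect_identical(small$z, big$z[idx])

  again <- generate_sites(fcc_lattice(1.128), 3.0)
  expect_identical(big, again)
})

test_that("every site has exactly 12 neighbors at the lattice spacing", {
  lat <- fcc_lattice(1.128, origin = c(0.3, -0.2, 1.0))
  s <- generate_sites(lat, 3.5)
  set.seed(2)
  for (id in sample(s$id, 20)) {
    nb <- site_neighbors(lat, id)
    expect_length(nb, 12)
    d <- sqrt(rowSums((site_position(lat, nb) -
                         matrix(site_position(lat, id), 12, 3,
                                byrow = TRUE))^2))
    expect_true(all(abs(d - 1.128) < 1e-9))
    # symmetry of the neighbor relation
    for (nid in nb[sample(12, 3)])
      expect_true(id %in% site_neighbors(lat, nid))
  }
})

test_that("occupancy bookkeeping stays bijective and audited", {
  lat <- fcc_lattice(1.0)
  s <- generate_sites(lat, 2.2)
  occ <- site_occupancy()
  picks <- s$id[seq(1, 40, by = 3)]
  for (q in seq_along(picks)) assign_site(occ, q, picks[q])
  expect_true(audit_occupancy(occ))
  expect_error(assign_site(occ, 99, picks[1]), "occupied")
  expect_error(assign_site(occ, 1, s$id[2]), "already assigned")
  freed <- release_site(occ, 3)
  expect_equal(freed, picks[3])
  expect_true(audit_occupancy(occ))
  expect_true(is.na(site_of_particle(occ, 3)))
  expect_true(is.na(particle_of_site(occ, picks[3])))
})

test_that("vacant and occupied neighbor counts always sum to 12", {
  lat <- fcc_lattice(1.128)
  s <- generate_sites(lat, 3.0)

  # isolated particle
  origin_id <- s$id[s$i == 0 & s$j == 0 & s$k == 0]
  occ <- site_occupancy(1, origin_id)
  expect_length(vacant_neighbor_sites(1, occ, lat), 12)
  expect_length(occupied_neighbor_particles(1, occ, lat), 0)

  # filled 13-site shell
  shell <- generate_sites(lat, 1.2)
  occ <- site_occupancy(1:13, shell$id)
  center <- which(shell$i == 0 & shell$j == 0 & shell$k == 0)
  expect_length(vacant_neighbor_sites(center, occ, lat), 0)
  expect_length(occupied_neighbor_particles(center, occ, lat), 12)

  # a shell particle: enumeration oracle by explicit distance scan
  p <- which(shell$i != 0 | shell$j != 0 | shell$k != 0)[1]
  nb <- site_neighbors(lat, shell$id[p])
  occupied <- sum(nb %in% shell$id)
  expect_length(occupied_neighbor_particles(p, occ, lat), occupied)
  expect_length(vacant_neighbor_sites(p, occ, lat), 12 - occupied)

  # random occupancy patterns
  set.seed(9)
  for (rep in 1:10) {
    rows <- sample(nrow(s), 15)
    occ <- site_occupancy(1:15, s$id[rows])
    j <- sample(15, 1)
    nvac <- length(vacant_neighbor_sites(j, occ, lat))
    nin <- length(occupied_neighbor_particles(j, occ, lat))
    expect_equal(nvac + nin, 12)
    # brute-force adjacency scan
    d <- sqrt(rowSums((site_position(lat, s$id[rows]) -
                         matrix(site_position(lat, s$id[rows[j]]), 15, 3,
                                byrow = TRUE))^2))
    expect_equal(nin, sum(abs(d - 1.128) < 1e-9))
  }

  expect_error(vacant_neighbor_sites(99, occ, lat), "not assigned")
})

test_that("nearest site breaks ties to the lowest id", {
  lat <- fcc_lattice(1.0)
  generate_sites(lat, 2)
  # midpoint between the origin site and a neighbor is equidistant
  nb <- site_neighbors(lat, 0)
  mid <- site_position(lat, nb[1]) / 2
  got <- nearest_site(lat, mid)
  expect_equal(got, min(0, nb[1]))
  # a position clearly nearest the origin (id 0 encodes the origin site)
  expect_equal(nearest_site(lat, c(0.05, -0.02, 0.01)), 0)
})
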