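# shared fixtures and independent oracles (kept deliberately naive)

# brute-force double-loop pair sum, independent of the compiled kernels
brute_energy <- function(pos, eps = 1, sigma = 1, cutoff = NULL,
                         box = NULL) {
  n <- nrow(pos)
  if (n < 2) return(0)
  e <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      d <- pos[i, ] - pos[j, ]
      if (!is.null(box)) d <- d - box * round(d / box)
      r <- sqrt(sum(d^2))
      if (!is.null(cutoff) && r > cutoff) next
      e <- e + 4 * eps * ((sigma / r)^12 - (sigma / r)^6)
    }
  }
  e
}

# center particle plus its 12 FCC nearest neighbors
fcc13 <- function(spacing = 1.128) {
  lat <- fcc_lattice(spacing)
  s <- generate_sites(lat, spacing * 1.05)
  as.matrix(s[, c("x", "y", "z")])
}

# random 3D rotation matrix
random_rotation <- function(seed) {
  set.seed(seed)
  m <- matrix(rnorm(9), 3, 3)
  qr.Q(qr(m)) * sample(c(-1, 1), 1)
}

# tiny three-site connected lattice model used by the oracle tests
three_site_model <- function(spacing = 1.128) {
  lat <- fcc_lattice(spacing)
  s <- generate_sites(lat, spacing * 1.05)
  list(lattice = lat, sites = s[c(1, 7, 13), ])
}

# multinomial size sampler drawing iid from exp(-beta (G + eta)); acts as
# a perfectly mixed stand-in for the MC engine in umbrella tests
synthetic_size_histogram <- function(n, g, eta, temperature, draws,
                                     n_blocks = 5, seed = 1) {
  set.seed(seed)
  p <- exp(-(g + eta) / temperature)
  p <- p / sum(p)
  counts <- vapply(seq_len(n_blocks), function(b)
    as.numeric(stats::rmultinom(1, draws, p)), numeric(length(n)))
  size_histogram(n, counts)
}
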