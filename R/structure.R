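# structural diagnostics: coordination numbers, Steinhardt Q6 and
# site-displacement distributions

.as_positions <- function(x) {
  if (inherits(x, "cluster_state")) return(x$config$positions)
  if (inherits(x, "particle_config")) return(x$positions)
  as.matrix(x)
}

# pair list (i, j, unit vector) for pairs closer than cutoff; chunked so
# large configurations never allocate an N x N matrix
.neighbor_pairs <- function(pos, cutoff, chunk = 512L) {
  n <- nrow(pos)
  res_i <- list()
  res_j <- list()
  res_d <- list()
  q <- 1L
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    block <- pos[lo:hi, , drop = FALSE]
    dx <- outer(block[, 1], pos[, 1], "-")
    dy <- outer(block[, 2], pos[, 2], "-")
    dz <- outer(block[, 3], pos[, 3], "-")
    d2 <- dx^2 + dy^2 + dz^2
    hit <- which(d2 < cutoff^2 & d2 > 0, arr.ind = TRUE)
    gi <- hit[, 1] + lo - 1L
    gj <- hit[, 2]
    keep <- gi < gj
    if (any(keep)) {
      res_i[[q]] <- gi[keep]
      res_j[[q]] <- gj[keep]
      res_d[[q]] <- cbind(dx[hit][keep], dy[hit][keep], dz[hit][keep])
      q <- q + 1L
    }
  }
  if (length(res_i) == 0)
    return(list(i = integer(0), j = integer(0),
                v = matrix(numeric(0), 0, 3)))
  list(i = unlist(res_i), j = unlist(res_j), v = do.call(rbind, res_d))
}

#' Coordination-number histogram and surface-particle count
#'
#' Counts, for every particle, the neighbors closer than `cutoff` and
#' reports the fraction of particles at each coordination number. Surface
#' particles are defined as those with fewer than 9 neighbors; in compact
#' FCC-like clusters their number scales with `n^(2/3)`.
#'
#' @param x Coordinates: a matrix, [particle_config()] or
#'   [cluster_state()].
#' @param cutoff Neighbor cutoff (default 1.5, near the first minimum of
#'   the LJ pair-correlation function).
#' @return List with `histogram` (data frame `coordination`, `fraction`),
#'   `surface_count`, `coordination` (per-particle counts) and `cutoff`.
#' @export
coordination_histogram <- function(x, cutoff = 1.5) {
  stopifnot(cutoff > 0)
  pos <- .as_positions(x)
  n <- nrow(pos)
  if (n == 0) stop("empty configuration")
  pr <- .neighbor_pairs(pos, cutoff)
  coord <- tabulate(c(pr$i, pr$j), nbins = n)
  tab <- table(factor(coord, levels = 0:max(coord, 0)))
  hist <- data.frame(coordination = as.integer(names(tab)),
                     fraction = as.numeric(tab) / n)
  list(histogram = hist, surface_count = sum(coord < 9),
       coordination = coord, cutoff = cutoff)
}

# associated Legendre P_6^m (Condon-Shortley phase dropped: only |sums|
# enter Q6) and the spherical-harmonic norms
.p6m <- function(m, c, s) {
  switch(as.character(m),
    "0" = (231 * c^6 - 315 * c^4 + 105 * c^2 - 5) / 16,
    "1" = (21 / 8) * c * (33 * c^4 - 30 * c^2 + 5) * s,
    "2" = (105 / 8) * (33 * c^4 - 18 * c^2 + 1) * s^2,
    "3" = (315 / 2) * c * (11 * c^2 - 3) * s^3,
    "4" = (945 / 2) * (11 * c^2 - 1) * s^4,
    "5" = 10395 * c * s^5,
    "6" = 10395 * s^6)
}

#' Global Steinhardt bond-orientational order parameter Q6
#'
#' `Q6 = sqrt( (4 pi / 13) sum_m | <Y_6m> |^2 )` with the spherical
#' harmonics averaged over ALL neighbor bonds of the configuration (the
#' global-average convention; the per-particle-averaged variant differs
#' numerically). Near 0.574 for perfect FCC, near zero (like
#' `N_bonds^(-1/2)`) for disordered structures.
#'
#' @inheritParams coordination_histogram
#' @return The scalar Q6 in `[0, 1]`.
#' @export
q6_global <- function(x, cutoff = 1.5) {
  pos <- .as_positions(x)
  pr <- .neighbor_pairs(pos, cutoff)
  nb <- length(pr$i)
  if (nb == 0) stop("no neighbor bonds: Q6 is undefined")
  r <- sqrt(rowSums(pr$v^2))
  cth <- pr$v[, 3] / r
  sth <- sqrt(pmax(0, 1 - cth^2))
  phi <- atan2(pr$v[, 2], pr$v[, 1])
  total <- 0
  for (m in 0:6) {
    norm <- sqrt((13 / (4 * pi)) * factorial(6 - m) / factorial(6 + m))
    qm <- mean(norm * .p6m(m, cth, sth) * exp(1i * m * phi))
    total <- total + (if (m == 0) 1 else 2) * Mod(qm)^2
  }
  sqrt(4 * pi / 13 * total)
}

#' Distribution of particle displacements from their lattice sites
#'
#' Histogram (normalized to unit area) of the distance between each
#' particle and its assigned site, binned at `bin_width`.
#'
#' @param x A solid [cluster_state()], or an N x 3 coordinate matrix (then
#'   `site_positions` is required).
#' @param site_positions N x 3 matrix of assigned-site coordinates.
#' @param bin_width Bin width (default 0.005).
#' @return List with `histogram` (data frame `distance` at bin centers,
#'   `density`) and the raw `distances`.
#' @export
site_displacement_histogram <- function(x, site_positions = NULL,
                                        bin_width = 0.005) {
  if (inherits(x, "cluster_state")) {
    stopifnot(x$mode == "solid")
    site_positions <- site_position(x$lattice, x$site_ids)
  }
  pos <- .as_positions(x)
  stopifnot(!is.null(site_positions), nrow(site_positions) == nrow(pos))
  d <- sqrt(rowSums((pos - site_positions)^2))
  n_bins <- max(1L, ceiling(max(d, bin_width) / bin_width))
  breaks <- seq(0, n_bins * bin_width, by = bin_width)
  counts <- tabulate(findInterval(d, breaks, rightmost.closed = TRUE),
                     nbins = n_bins)
  density <- counts / (length(d) * bin_width)
  list(histogram = data.frame(distance = breaks[-1] - bin_width / 2,
                              density = density),
       distances = d)
}
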