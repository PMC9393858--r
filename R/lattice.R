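# FCC geometry uses the parity representation: sites are integer triples
# (i, j, k) with i + j + k even, scaled by half the conventional cell edge
# a/2 = spacing / sqrt(2). Nearest neighbors are the 12 offsets of type
# (+-1, +-1, 0), at distance `spacing`.

.fcc_offsets <- local({
  m <- rbind(
    c(1, 1, 0), c(1, -1, 0), c(-1, 1, 0), c(-1, -1, 0),
    c(1, 0, 1), c(1, 0, -1), c(-1, 0, 1), c(-1, 0, -1),
    c(0, 1, 1), c(0, 1, -1), c(0, -1, 1), c(0, -1, -1))
  storage.mode(m) <- "integer"
  m
})

# zig-zag map Z -> N so triples encode into one exact double (< 2^53)
.zig <- function(n) ifelse(n >= 0, 2 * n, -2 * n - 1)
.unzig <- function(z) ifelse(z %% 2 == 0, z / 2, -(z + 1) / 2)

.encode_site <- function(i, j, k) {
  (.zig(i) * 2^17 + .zig(j)) * 2^17 + .zig(k)
}

.decode_site <- function(id) {
  k <- id %% 2^17
  rest <- (id - k) / 2^17
  j <- rest %% 2^17
  i <- (rest - j) / 2^17
  cbind(i = .unzig(i), j = .unzig(j), k = .unzig(k))
}

#' Face-centered cubic lattice
#'
#' An FCC lattice anchored at `origin` with nearest-neighbor spacing
#' `spacing` (so the conventional cubic cell edge is `spacing * sqrt(2)`).
#' Sites are generated on demand and carry ids that are stable under
#' extension: an id encodes the site's integer coordinates, so growing the
#' generated region never renumbers existing sites.
#'
#' @param spacing Nearest-neighbor distance (> 0, sigma units).
#' @param origin Numeric length-3 anchor; the origin is itself a site.
#' @return An object of class `fcc_lattice`.
#' @export
fcc_lattice <- function(spacing, origin = c(0, 0, 0)) {
  stopifnot(is.numeric(spacing), length(spacing) == 1, spacing > 0)
  stopifnot(is.numeric(origin), length(origin) == 3)
  structure(list(spacing = spacing, origin = as.numeric(origin),
                 half = spacing / sqrt(2), state = new.env(parent = emptyenv())),
            class = "fcc_lattice")
}

#' @export
print.fcc_lattice <- function(x, ...) {
  cat(sprintf("fcc_lattice: spacing %g (cell edge %g), origin (%g, %g, %g)\n",
              x$spacing, x$spacing * sqrt(2),
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Generate all lattice sites within a radius
#'
#' Deterministically enumerates every site within `extent` of the lattice
#' origin, ordered lexicographically by integer coordinates. Successive
#' calls with a growing extent reproduce earlier sites with identical ids
#' and coordinates.
#'
#' @param lattice An [fcc_lattice()].
#' @param extent Radius around the origin (>= 0).
#' @return A data frame with columns `id`, `i`, `j`, `k`, `x`, `y`, `z`.
#' @export
generate_sites <- function(lattice, extent) {
  stopifnot(extent >= 0)
  h <- lattice$half
  m <- as.integer(ceiling(extent / h)) + 1L
  g <- expand.grid(k = -m:m, j = -m:m, i = -m:m)  # k fastest: lexicographic in (i,j,k)
  g <- g[(g$i + g$j + g$k) %% 2 == 0, c("i", "j", "k")]
  x <- lattice$origin[1] + h * g$i
  y <- lattice$origin[2] + h * g$j
  z <- lattice$origin[3] + h * g$k
  r2 <- (x - lattice$origin[1])^2 + (y - lattice$origin[2])^2 +
    (z - lattice$origin[3])^2
  keep <- r2 <= extent^2 + 1e-12
  out <- data.frame(id = .encode_site(g$i[keep], g$j[keep], g$k[keep]),
                    i = g$i[keep], j = g$j[keep], k = g$k[keep],
                    x = x[keep], y = y[keep], z = z[keep])
  out <- out[order(out$i, out$j, out$k), , drop = FALSE]
  rownames(out) <- NULL
  lattice$state$extent <- max(extent, lattice$state$extent %||% 0)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cartesian position of lattice sites
#'
#' @param lattice An [fcc_lattice()].
#' @param id Site id(s).
#' @return Matrix with one row per id.
#' @export
site_position <- function(lattice, id) {
  ijk <- .decode_site(id)
  sweep(ijk * lattice$half, 2, lattice$origin, "+",
        check.margin = FALSE)
}

#' The 12 nearest-neighbor sites of a site
#'
#' @param lattice An [fcc_lattice()].
#' @param id A single site id.
#' @return Numeric vector of 12 site ids (generated on demand).
#' @export
site_neighbors <- function(lattice, id) {
  stopifnot(length(id) == 1)
  ijk <- .decode_site(id)
  .encode_site(ijk[, 1] + .fcc_offsets[, 1],
               ijk[, 2] + .fcc_offsets[, 2],
               ijk[, 3] + .fcc_offsets[, 3])
}

#' Particle-site occupancy bookkeeping
#'
#' A bidirectional association between particle indices and lattice-site
#' ids. Each site holds at most one particle; each particle sits on exactly
#' one site. The two maps are kept mutually inverse by construction and can
#' be audited with [audit_occupancy()].
#'
#' @param particles Optional integer vector of particle indices.
#' @param sites Optional site ids, parallel to `particles`.
#' @return An object of class `site_occupancy`.
#' @export
site_occupancy <- function(particles = integer(), sites = numeric()) {
  stopifnot(length(particles) == length(sites))
  occ <- structure(list(p2s = new.env(parent = emptyenv()),
                        s2p = new.env(parent = emptyenv())),
                   class = "site_occupancy")
  for (q in seq_along(particles))
    assign_site(occ, particles[q], sites[q])
  occ
}

#' @export
print.site_occupancy <- function(x, ...) {
  cat(sprintf("site_occupancy: %d assigned particles\n",
              length(ls(x$p2s))))
  invisible(x)
}

#' Assign a particle to a vacant site
#'
#' @param occ A [site_occupancy()].
#' @param particle Particle index.
#' @param site Site id.
#' @return Invisibly, `occ` (modified in place).
#' @export
assign_site <- function(occ, particle, site) {
  ps <- as.character(particle)
  ss <- as.character(site)
  if (!is.null(occ$s2p[[ss]]))
    stop("site already occupied: each site can hold at most one particle")
  if (!is.null(occ$p2s[[ps]])) stop("particle already assigned")
  occ$p2s[[ps]] <- site
  occ$s2p[[ss]] <- particle
  invisible(occ)
}

#' Release a particle's site
#'
#' @param occ A [site_occupancy()].
#' @param particle Particle index.
#' @return Invisibly, the freed site id.
#' @export
release_site <- function(occ, particle) {
  ps <- as.character(particle)
  site <- occ$p2s[[ps]]
  if (is.null(site)) stop("particle is not assigned to any site")
  rm(list = ps, envir = occ$p2s)
  rm(list = as.character(site), envir = occ$s2p)
  invisible(site)
}

#' Site of a particle / particle on a site
#'
#' @param occ A [site_occupancy()].
#' @param particle Particle index.
#' @return Site id, or `NA` if unassigned.
#' @export
site_of_particle <- function(occ, particle) {
  occ$p2s[[as.character(particle)]] %||% NA_real_
}

#' @rdname site_of_particle
#' @param site Site id.
#' @export
particle_of_site <- function(occ, site) {
  occ$s2p[[as.character(site)]] %||% NA_integer_
}

#' Audit that the occupancy maps are mutually inverse
#'
#' @param occ A [site_occupancy()].
#' @return `TRUE` (invisibly) or an error describing the inconsistency.
#' @export
audit_occupancy <- function(occ) {
  for (p in ls(occ$p2s)) {
    s <- occ$p2s[[p]]
    back <- occ$s2p[[as.character(s)]]
    if (is.null(back) || as.character(back) != p)
      stop(sprintf("occupancy maps are not inverse at particle %s", p))
  }
  if (length(ls(occ$p2s)) != length(ls(occ$s2p)))
    stop("occupancy maps differ in size")
  invisible(TRUE)
}

#' Vacant lattice sites adjacent to a particle's site
#'
#' The candidate insertion sites of the lattice-based AVB swap move: the
#' vacant sites among the 12 nearest neighbors of the site that particle
#' `particle` occupies. `N_in + N_vac = 12` always.
#'
#' @param particle Particle index (must be assigned).
#' @param occ A [site_occupancy()].
#' @param lattice An [fcc_lattice()].
#' @return Numeric vector of vacant neighbor site ids (length `N_vac`).
#' @export
vacant_neighbor_sites <- function(particle, occ, lattice) {
  s <- site_of_particle(occ, particle)
  if (is.na(s)) stop("particle is not assigned to any site")
  nb <- site_neighbors(lattice, s)
  nb[vapply(nb, function(id) is.null(occ$s2p[[as.character(id)]]), logical(1))]
}

#' Particles occupying sites adjacent to a particle's site
#'
#' The deletion candidates of the lattice-based AVB swap move (length
#' `N_in`); an isolated particle returns an empty vector, and such deletion
#' attempts are automatically rejected by the move.
#'
#' @inheritParams vacant_neighbor_sites
#' @return Integer vector of particle indices (length `N_in`).
#' @export
occupied_neighbor_particles <- function(particle, occ, lattice) {
  s <- site_of_particle(occ, particle)
  if (is.na(s)) stop("particle is not assigned to any site")
  nb <- site_neighbors(lattice, s)
  out <- unlist(lapply(nb, function(id) occ$s2p[[as.character(id)]]))
  if (is.null(out)) integer(0) else as.integer(out)
}

#' Nearest lattice site of a position
#'
#' Used by audits only (assignments are carried through moves, not
#' recomputed). Ties between equidistant sites break to the lowest id.
#'
#' @param lattice An [fcc_lattice()].
#' @param position Numeric length-3 coordinates.
#' @return The site id.
#' @export
nearest_site <- function(lattice, position) {
  h <- lattice$half
  u <- (as.numeric(position) - lattice$origin) / h
  base <- floor(u)
  wide <- expand.grid(di = -1:2, dj = -1:2, dk = -1:2)
  i <- base[1] + wide$di; j <- base[2] + wide$dj; k <- base[3] + wide$dk
  ok <- (i + j + k) %% 2 == 0
  i <- i[ok]; j <- j[ok]; k <- k[ok]
  d2 <- (u[1] - i)^2 + (u[2] - j)^2 + (u[3] - k)^2
  ids <- .encode_site(i, j, k)
  best <- d2 <= min(d2) + 1e-12
  min(ids[best])
}

# Dense site tables for the compiled engine: site coordinates plus a
# 0-based neighbor index matrix (-1 where the neighbor falls outside the
# generated set).
.site_tables <- function(lattice, extent = NULL, sites = NULL) {
  if (is.null(sites)) sites <- generate_sites(lattice, extent)
  pos <- as.matrix(sites[, c("x", "y", "z")])
  nbr <- matrix(-1L, nrow(sites), 12)
  for (q in 1:12) {
    nid <- .encode_site(sites$i + .fcc_offsets[q, 1],
                        sites$j + .fcc_offsets[q, 2],
                        sites$k + .fcc_offsets[q, 3])
    idx <- match(nid, sites$id)
    nbr[, q] <- ifelse(is.na(idx), -1L, as.integer(idx - 1L))
  }
  list(sites = sites, pos = pos, nbr = nbr)
}
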