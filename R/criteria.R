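#' Liquid (Stillinger) cluster criterion
#'
#' A configuration is one liquid cluster when the graph whose edges join
#' pairs closer than `R` (strict inequality) is connected. Zero or one
#' particle counts as a valid cluster.
#'
#' @param config A cluster-mode [particle_config()].
#' @param R Stillinger radius; also the AVB insertion radius (the two are
#'   one parameter here).
#' @return `TRUE` or `FALSE`.
#' @export
liquid_cluster_ok <- function(config, R) {
  stopifnot(R > 0, config$mode == "cluster")
  pos <- config$positions
  n <- nrow(pos)
  if (n <= 1) return(TRUE)
  d <- as.matrix(stats::dist(pos))
  adj <- d < R
  diag(adj) <- FALSE
  seen <- logical(n)
  stack <- 1L
  seen[1] <- TRUE
  while (length(stack)) {
    p <- stack[length(stack)]
    stack <- stack[-length(stack)]
    nxt <- which(adj[p, ] & !seen)
    seen[nxt] <- TRUE
    stack <- c(stack, nxt)
  }
  all(seen)
}

#' Solid (lattice) cluster criterion
#'
#' A solid cluster is valid when (a) every particle lies within `r`
#' (inclusive) of its assigned lattice site and (b) the occupied sites form
#' a connected set under the 12-neighbor FCC adjacency.
#'
#' @param config A cluster-mode [particle_config()].
#' @param occ A [site_occupancy()] assigning every particle `1..N`.
#' @param lattice The [fcc_lattice()].
#' @param r Site-binding radius. Values above half the lattice spacing are
#'   allowed but warned against (binding spheres then overlap).
#' @return `TRUE` or `FALSE`.
#' @export
solid_cluster_ok <- function(config, occ, lattice, r) {
  stopifnot(r > 0, config$mode == "cluster")
  if (r > lattice$spacing / 2)
    warning("site-binding radius exceeds half the lattice spacing")
  pos <- config$positions
  n <- nrow(pos)
  if (n == 0) return(TRUE)
  sites <- vapply(seq_len(n), function(p) {
    s <- site_of_particle(occ, p)
    if (is.na(s)) stop(sprintf("particle %d has no assigned site", p))
    s
  }, numeric(1))
  sp <- site_position(lattice, sites)
  d <- sqrt(rowSums((pos - sp)^2))
  if (any(d > r)) return(FALSE)
  if (n == 1) return(TRUE)
  # connectivity of occupied sites under FCC adjacency
  seen <- logical(n)
  seen[1] <- TRUE
  stack <- 1L
  while (length(stack)) {
    p <- stack[length(stack)]
    stack <- stack[-length(stack)]
    nb <- site_neighbors(lattice, sites[p])
    nxt <- which(sites %in% nb & !seen)
    seen[nxt] <- TRUE
    stack <- c(stack, nxt)
  }
  all(seen)
}
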