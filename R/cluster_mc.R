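#' Ideal-gas reservoir specification
#'
#' The cluster is coupled to an ideal gas reservoir at temperature `T` and
#' number density `n_v`. The chemical potential convention is
#' `beta * mu_gas = ln(n_v * sigma^3)`, so `n_v = 1` corresponds to
#' `mu_gas = 0` excluding the kinetic term.
#'
#' @param temperature Reduced temperature (> 0).
#' @param density Reservoir number density `n_v` (> 0).
#' @return An object of class `reservoir_spec`.
#' @export
reservoir_spec <- function(temperature, density = 1) {
  stopifnot(temperature > 0, density > 0)
  structure(list(temperature = temperature, beta = 1 / temperature,
                 density = density,
                 mu_gas = temperature * log(density)),
            class = "reservoir_spec")
}

#' Move parameters for cluster Monte Carlo
#'
#' `radius` is the AVB insertion radius: the Stillinger/insertion radius
#' `R` for liquid clusters, or the site-binding radius `r` for solid
#' clusters. The insertion volume is `V_in = (4/3) pi radius^3` exactly
#' (insertion points are drawn uniformly in the sphere by radius-cubed
#' inversion).
#'
#' @param radius Insertion radius (> 0).
#' @param max_displacement Translation cap for liquid clusters (default 0.2).
#' @return An object of class `move_params`.
#' @export
move_params <- function(radius, max_displacement = 0.2) {
  stopifnot(radius > 0, max_displacement > 0)
  structure(list(radius = radius, v_in = 4 / 3 * pi * radius^3,
                 max_displacement = max_displacement),
            class = "move_params")
}

#' Inclusive cluster-size window
#'
#' Proposals that would leave `[n_min, n_max]` are auto-rejected, which
#' implements the sparse-window sampling strategy; free-energy increments
#' only need adjacent-size ratios, which windows preserve.
#'
#' @param n_min,n_max Inclusive bounds, `1 <= n_min <= n_max`.
#' @return An object of class `size_window`.
#' @export
size_window <- function(n_min, n_max) {
  stopifnot(n_min >= 1, n_min <= n_max)
  structure(list(n_min = as.integer(n_min), n_max = as.integer(n_max)),
            class = "size_window")
}

#' Cluster simulation state
#'
#' Bundles the particle coordinates with, for solid clusters, the lattice
#' and the per-particle site assignment.
#'
#' @param positions N x 3 coordinate matrix (open space).
#' @param mode `"solid"` or `"liquid"`.
#' @param lattice An [fcc_lattice()] (solid mode).
#' @param site_ids Numeric vector of site ids, one per particle (solid
#'   mode); must be distinct.
#' @return An object of class `cluster_state`.
#' @export
cluster_state <- function(positions, mode = c("solid", "liquid"),
                          lattice = NULL, site_ids = NULL) {
  mode <- match.arg(mode)
  config <- particle_config(positions, mode = "cluster")
  n <- nrow(config$positions)
  if (n < 1) stop("empty cluster")
  if (mode == "solid") {
    if (is.null(lattice) || is.null(site_ids))
      stop("solid mode requires a lattice and site assignments")
    if (length(site_ids) != n) stop("one site id per particle required")
    if (anyDuplicated(site_ids)) stop("each site can hold at most one particle")
  }
  structure(list(config = config, mode = mode, lattice = lattice,
                 site_ids = site_ids), class = "cluster_state")
}

#' @export
print.cluster_state <- function(x, ...) {
  cat(sprintf("cluster_state: %d particles, %s cluster\n",
              nrow(x$config$positions), x$mode))
  invisible(x)
}

#' Size of a cluster state
#' @param state A [cluster_state()].
#' @return Number of particles.
#' @export
cluster_size <- function(state) nrow(state$config$positions)

#' Occupancy object of a solid cluster state
#' @param state A solid [cluster_state()].
#' @return A [site_occupancy()].
#' @export
state_occupancy <- function(state) {
  stopifnot(state$mode == "solid")
  site_occupancy(seq_len(cluster_size(state)), state$site_ids)
}

#' AVB swap acceptance argument
#'
#' The per-path detailed-balance acceptance argument of the four swap
#' variants (the acceptance probability is `min(1, argument)`). Counts are
#' evaluated in the pre-move state. For the lattice variant:
#' insertion `n_v V_in e^(-beta dE) N N_vac / ((N+1)(N_in+1))`,
#' deletion `e^(-beta dE) / (n_v V_in) * N N_in / ((N-1)(N_vac+1))`.
#' For the original variant: insertion
#' `n_v V_in e^(-beta dE) N / ((N+1)(N_in+1))`, deletion
#' `e^(-beta dE) / (n_v V_in) * N N_in / (N-1)` (the reverse insertion
#' targets the same particle j among the N-1 survivors).
#' `dE` here includes any bias increment `eta(n') - eta(n)`.
#'
#' @param kind `"insert"` or `"delete"`.
#' @param variant `"lattice"` or `"original"`.
#' @param N Pre-move cluster size.
#' @param N_in Occupied-neighbor count of the target particle.
#' @param N_vac Vacant-neighbor count (lattice variant only).
#' @param delta_E Energy change of the move (plus bias increment).
#' @param beta Inverse temperature.
#' @param n_v Reservoir density.
#' @param v_in Insertion volume.
#' @return The acceptance argument (not clamped to 1).
#' @export
acceptance_argument <- function(kind = c("insert", "delete"),
                                variant = c("lattice", "original"),
                                N, N_in, N_vac = NULL, delta_E, beta, n_v,
                                v_in) {
  kind <- match.arg(kind)
  variant <- match.arg(variant)
  boltz <- exp(-beta * delta_E)
  if (variant == "lattice") {
    stopifnot(!is.null(N_vac))
    if (kind == "insert")
      n_v * v_in * boltz * N * N_vac / ((N + 1) * (N_in + 1))
    else
      boltz / (n_v * v_in) * N * N_in / ((N - 1) * (N_vac + 1))
  } else {
    if (kind == "insert")
      n_v * v_in * boltz * N / ((N + 1) * (N_in + 1))
    else
      boltz / (n_v * v_in) * N * N_in / (N - 1)
  }
}

# dense engine inputs for a state; extent covers the window generously so
# the replicating lattice never runs out of complete neighbor shells
.engine_inputs <- function(state, window) {
  if (state$mode == "liquid") {
    return(list(site_pos = matrix(numeric(0), 0, 3),
                site_nbr = matrix(integer(0), 0, 12),
                occ0 = integer(0), sites = NULL))
  }
  lat <- state$lattice
  site_density <- sqrt(2) / lat$spacing^3
  ball <- (3 * window$n_max / (4 * pi * site_density))^(1 / 3)
  extent <- 1.8 * ball + 3 * lat$spacing
  tab <- .site_tables(lat, extent)
  occ0 <- match(state$site_ids, tab$sites$id)
  if (anyNA(occ0))
    stop("occupied site outside generated lattice extent")
  list(site_pos = tab$pos, site_nbr = tab$nbr,
       occ0 = as.integer(occ0 - 1L), sites = tab$sites)
}

.state_from_engine <- function(state, out, sites) {
  if (state$mode == "solid") {
    cluster_state(out$xyz, "solid", lattice = state$lattice,
                  site_ids = sites$id[out$occ + 1L])
  } else {
    cluster_state(out$xyz, "liquid")
  }
}

.bias_vector <- function(bias, window) {
  n <- window$n_min:window$n_max
  if (is.null(bias)) return(numeric(length(n)))
  eta <- bias_value(bias, n)
  if (anyNA(eta))
    stop("bias potential does not cover the whole size window")
  eta
}

#' Run grand-canonical cluster Monte Carlo
#'
#' Samples `pi(state) proportional to exp(-beta (U + eta(n)))` restricted to
#' a size window, using AVB swap moves mixed 50/50 (by default) with
#' intrasite jumps (solid) or translations (liquid). Returns the
#' visited-size histogram split into blocks, per-move-type acceptance
#' statistics, and the final state.
#'
#' @param state Initial [cluster_state()] (must satisfy its cluster
#'   criterion and lie inside the window).
#' @param reservoir A [reservoir_spec()].
#' @param params A [move_params()].
#' @param window A [size_window()].
#' @param bias A [bias_potential()] covering the window, or `NULL` for no
#'   bias.
#' @param n_moves Total move attempts.
#' @param seed Integer RNG seed; identical seeds give bit-identical runs.
#' @param p_swap Probability of attempting a swap (vs jump/translate).
#' @param sample_every Record the size histogram every this many moves.
#' @param energy_mode `"lj"` (full pair sum), `"ideal"` (no interactions) or
#'   `"frozen"` (pair energies at site centers; solid only). The last two
#'   exist for the exact-enumeration validation models.
#' @param spec An [lj_spec()] without cutoff.
#' @param n_blocks Number of error-estimation blocks (default 5).
#' @param track_patterns Record occupancy bit patterns (tiny solid models
#'   only, at most 32 sites).
#' @param log_moves Keep a per-move log (kind, energy change, acceptance
#'   argument, outcome) for the first 2e5 moves.
#' @param traj_every If positive, collect a thinned trajectory snapshot
#'   every this many moves (the run is split into segments with derived
#'   seeds; results remain seed-reproducible).
#' @param .drop_count_factor Deliberately corrupt the acceptance rule by
#'   dropping the proposal-counting factor; negative control for the
#'   enumeration oracle. Never use in production.
#' @param .engine Precomputed engine inputs (internal).
#' @return A list with `histogram` ([size_histogram()]), `stats`
#'   (per-move-type attempts/accepts), `state` (final [cluster_state()]),
#'   `patterns`, `move_log`, `trajectory`, `energy`, `audit`.
#' @export
run_gc_cluster <- function(state, reservoir, params, window, bias = NULL,
                           n_moves, seed, p_swap = 0.5, sample_every = 1,
                           energy_mode = c("lj", "ideal", "frozen"),
                           spec = lj_spec(), n_blocks = 5,
                           track_patterns = FALSE, log_moves = FALSE,
                           traj_every = 0, .drop_count_factor = FALSE,
                           .engine = NULL) {
  energy_mode <- match.arg(energy_mode)
  if (!is.null(spec$cutoff)) stop("cluster simulations use no cutoff")
  n0 <- cluster_size(state)
  if (n0 < window$n_min || n0 > window$n_max)
    stop("initial cluster size outside the window")
  eng <- .engine %||% .engine_inputs(state, window)
  eta <- .bias_vector(bias, window)
  mode_i <- if (state$mode == "solid") 0L else 1L
  emode <- match(energy_mode, c("lj", "ideal", "frozen")) - 1L
  if (emode == 2L && mode_i == 1L) stop("frozen energies require solid mode")

  segments <- if (traj_every > 0) {
    sizes <- rep(traj_every, n_moves %/% traj_every)
    if (n_moves %% traj_every > 0) sizes <- c(sizes, n_moves %% traj_every)
    sizes
  } else n_moves

  cur <- state
  trajectory <- list()
  agg <- NULL
  occ0 <- eng$occ0
  xyz <- cur$config$positions
  for (si in seq_along(segments)) {
    out <- cpp_run_cluster(xyz, mode_i, eng$site_pos, eng$site_nbr, occ0,
                           reservoir$beta, reservoir$density, params$radius,
                           params$max_displacement, window$n_min,
                           window$n_max, eta, emode, spec$epsilon, spec$sigma,
                           segments[si], as.integer(seed + (si - 1L)),
                           n_blocks, p_swap, as.integer(sample_every),
                           track_patterns, .drop_count_factor, log_moves,
                           0L)
    xyz <- out$xyz
    occ0 <- out$occ
    if (is.null(agg)) {
      agg <- out
    } else {
      agg$counts <- agg$counts + out$counts
      for (f in c("att_insert", "acc_insert", "att_delete", "acc_delete",
                  "att_move", "acc_move"))
        agg[[f]] <- agg[[f]] + out[[f]]
      agg$xyz <- out$xyz
      agg$occ <- out$occ
      agg$energy <- out$energy
      agg$occupancy_ok <- agg$occupancy_ok && out$occupancy_ok
      agg$energy_drift <- max(abs(agg$energy_drift), abs(out$energy_drift))
    }
    if (traj_every > 0)
      trajectory[[si]] <- xyz
  }
  if (abs(agg$energy_drift) > 1e-7)
    warning(sprintf("cached energy drifted by %.3g against full recompute",
                    agg$energy_drift))

  hist <- size_histogram(agg$n_values, agg$counts)
  stats <- data.frame(
    move = c("insert", "delete", if (mode_i == 0L) "intrasite" else "translate"),
    attempts = c(agg$att_insert, agg$att_delete, agg$att_move),
    accepts = c(agg$acc_insert, agg$acc_delete, agg$acc_move))
  stats$rate <- ifelse(stats$attempts > 0, stats$accepts / stats$attempts, NA)

  final <- .state_from_engine(state, agg, eng$sites)
  list(histogram = hist, stats = stats, state = final,
       patterns = agg$patterns, move_log = agg$move_log,
       trajectory = trajectory, energy = agg$energy,
       audit = list(occupancy_ok = agg$occupancy_ok,
                    energy_drift = agg$energy_drift),
       seed = seed)
}

# shared single-move driver
.one_move <- function(state, reservoir, params, window, seed, p_swap,
                      energy_mode, bias = NULL, force_kind = 0L,
                      spec = lj_spec()) {
  eng <- .engine_inputs(state, window)
  eta <- .bias_vector(bias, window)
  mode_i <- if (state$mode == "solid") 0L else 1L
  emode <- match(energy_mode, c("lj", "ideal", "frozen")) - 1L
  out <- cpp_run_cluster(state$config$positions, mode_i, eng$site_pos,
                         eng$site_nbr, eng$occ0, reservoir$beta,
                         reservoir$density, params$radius,
                         params$max_displacement, window$n_min, window$n_max,
                         eta, emode, spec$epsilon, spec$sigma, 1, seed, 1,
                         p_swap, 1L, FALSE, FALSE, TRUE, as.integer(force_kind))
  lg <- out$move_log
  proposal <- structure(list(
    kind = c("insert", "delete", if (mode_i == 0L) "intrasite" else
      "translate")[lg$kind[1]],
    delta_E = lg$delta_E[1], accepted = lg$accepted[1] == 1,
    acceptance_arg = lg$arg[1]), class = "move_proposal")
  list(state = .state_from_engine(state, out, eng$sites),
       proposal = proposal)
}

#' Single lattice-based AVB swap move
#'
#' One insertion-or-deletion attempt (chosen with equal probability) of the
#' lattice-based AVB scheme: the target particle is uniform over the
#' cluster, insertions go to a uniformly chosen vacant neighbor site of the
#' target (uniform position within its binding sphere) and deletions remove
#' a uniformly chosen occupied neighbor, with per-path detailed-balance
#' acceptance (see [acceptance_argument()]). Auto-rejects when no vacant
#' site / no neighbor is available, when the residual cluster would break
#' the criterion, or when the window would be left.
#'
#' @inheritParams run_gc_cluster
#' @param seed Integer seed for the single draw.
#' @return List with the (possibly updated) `state` and the `proposal`
#'   (kind, `delta_E`, acceptance argument, accepted flag).
#' @export
lattice_avbmc_swap <- function(state, reservoir, params, window, seed,
                               bias = NULL,
                               energy_mode = c("lj", "ideal", "frozen"),
                               spec = lj_spec()) {
  stopifnot(state$mode == "solid")
  .one_move(state, reservoir, params, window, seed, 1, match.arg(energy_mode),
            bias, 0L, spec)
}

#' Single original AVB swap move
#'
#' One swap attempt of the original AVB scheme for liquid clusters: the
#' insertion volume is the sphere of radius `R` about the target particle.
#'
#' @inheritParams lattice_avbmc_swap
#' @return As [lattice_avbmc_swap()].
#' @export
original_avbmc_swap <- function(state, reservoir, params, window, seed,
                                bias = NULL,
                                energy_mode = c("lj", "ideal"),
                                spec = lj_spec()) {
  stopifnot(state$mode == "liquid")
  .one_move(state, reservoir, params, window, seed, 1, match.arg(energy_mode),
            bias, 0L, spec)
}

#' Single intrasite jump move
#'
#' Displaces one uniformly chosen particle to a uniform position within the
#' binding sphere of its own site; accepted with the bare Boltzmann factor.
#' The proposal can never violate the site-binding condition.
#'
#' @inheritParams lattice_avbmc_swap
#' @return As [lattice_avbmc_swap()].
#' @export
intrasite_jump <- function(state, reservoir, params, seed,
                           energy_mode = c("lj", "ideal", "frozen"),
                           spec = lj_spec()) {
  stopifnot(state$mode == "solid")
  n <- cluster_size(state)
  .one_move(state, reservoir, params, size_window(max(1, n - 1), n + 1),
            seed, 0, match.arg(energy_mode), NULL, 0L, spec)
}

#' Single translation move
#'
#' Uniform displacement in the cube `[-max_displacement, max_displacement]^3`
#' with Metropolis acceptance; rejected if the Stillinger criterion breaks.
#'
#' @inheritParams lattice_avbmc_swap
#' @return As [lattice_avbmc_swap()].
#' @export
translate_move <- function(state, reservoir, params, seed,
                           energy_mode = c("lj", "ideal"),
                           spec = lj_spec()) {
  stopifnot(state$mode == "liquid")
  n <- cluster_size(state)
  .one_move(state, reservoir, params, size_window(max(1, n - 1), n + 1),
            seed, 0, match.arg(energy_mode), NULL, 0L, spec)
}

#' Initial solid cluster: filled lattice shells
#'
#' Occupies the `n` lattice sites nearest the origin (ties broken by site
#' id), with each particle at its site center. Such a nearest-shell ball is
#' connected under the FCC adjacency.
#'
#' @param n Cluster size.
#' @param lattice An [fcc_lattice()].
#' @return A solid [cluster_state()].
#' @export
initial_solid_cluster <- function(n, lattice) {
  site_density <- sqrt(2) / lattice$spacing^3
  extent <- 1.6 * (3 * n / (4 * pi * site_density))^(1 / 3) +
    2 * lattice$spacing
  sites <- generate_sites(lattice, extent)
  r2 <- (sites$x - lattice$origin[1])^2 + (sites$y - lattice$origin[2])^2 +
    (sites$z - lattice$origin[3])^2
  ord <- order(r2, sites$id)
  chosen <- sites[ord[seq_len(n)], , drop = FALSE]
  cluster_state(as.matrix(chosen[, c("x", "y", "z")]), "solid",
                lattice = lattice, site_ids = chosen$id)
}

#' Initial liquid cluster: relaxed FCC ball
#'
#' Excises an FCC ball of `n` particles at near-melt spacing and relaxes it
#' with translation-only sweeps before use.
#'
#' @param n Cluster size.
#' @param reservoir A [reservoir_spec()] (sets the relaxation temperature).
#' @param params A [move_params()] (Stillinger radius and displacement cap).
#' @param seed Integer seed.
#' @param relax_sweeps Translation sweeps used for relaxation.
#' @param spacing Initial nearest-neighbor distance.
#' @return A liquid [cluster_state()].
#' @export
initial_liquid_cluster <- function(n, reservoir, params, seed,
                                   relax_sweeps = 1000, spacing = 2^(1 / 6)) {
  seed_lat <- fcc_lattice(spacing)
  solid <- initial_solid_cluster(n, seed_lat)
  state <- cluster_state(solid$config$positions, "liquid")
  if (relax_sweeps > 0) {
    out <- run_gc_cluster(state, reservoir, params,
                          size_window(n, n), bias = NULL,
                          n_moves = relax_sweeps * n, seed = seed, p_swap = 0,
                          sample_every = max(1, relax_sweeps %/% 10))
    state <- out$state
  }
  state
}
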