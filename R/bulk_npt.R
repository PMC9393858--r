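#' FCC-initialized cubic box configuration
#'
#' Builds `n = 4 k^3` particles on a perfect FCC lattice in a cubic box at
#' the requested density.
#'
#' @param n Particle count; must be of the form `4 k^3` (864 = 4 * 6^3).
#' @param density Number density.
#' @param partial Allow `n` below the full `4 k^3` (vacancies); used to
#'   seed liquid runs that are scrambled anyway.
#' @return A bulk [particle_config()].
#' @export
fcc_box_config <- function(n, density, partial = FALSE) {
  stopifnot(n >= 1, density > 0)
  k <- round((n / 4)^(1 / 3))
  if (4 * k^3 < n) k <- k + 1
  if (!partial && 4 * k^3 != n)
    stop("n must be 4 k^3 for an FCC-commensurate box (e.g. 864 = 4*6^3)")
  box <- (n / density)^(1 / 3)
  a <- box / k
  cell <- rbind(c(0, 0, 0), c(0, 0.5, 0.5), c(0.5, 0, 0.5), c(0.5, 0.5, 0))
  g <- expand.grid(i = 0:(k - 1), j = 0:(k - 1), l = 0:(k - 1))
  pos <- do.call(rbind, lapply(seq_len(nrow(g)), function(q)
    sweep(cell, 2, as.numeric(g[q, ]), "+")))
  pos <- pos[seq_len(n), , drop = FALSE] * a
  particle_config(pos, box_length = box, mode = "bulk")
}

#' Isobaric-isothermal Monte Carlo of bulk Lennard-Jones
#'
#' NPT Metropolis MC with single-particle translations and one volume move
#' per sweep (uniform in `ln V`, with the `(N+1) ln V` Jacobian weight).
#' The pair potential is truncated at `cutoff` with analytical tail
#' corrections applied to energy and virial. Volume proposals that would
#' shrink the box below twice the cutoff are rejected (the minimum-image
#' convention would otherwise break). Errors are estimated from 5 blocks.
#'
#' Solid runs start from a perfect FCC lattice; liquid runs start from an
#' FCC lattice that is melted by a short constant-volume scramble stage at
#' elevated temperature before equilibration.
#'
#' @param phase `"liquid"` or `"fcc_solid"`.
#' @param n_particles Particle count (solid: must be `4 k^3`).
#' @param temperature,pressure Reduced state point.
#' @param cutoff Truncation radius (default 4.75).
#' @param sweeps Production sweeps.
#' @param equil Equilibration sweeps (volume moves active).
#' @param seed Integer seed; identical seeds give bit-identical runs.
#' @param epsilon,sigma LJ parameters (`epsilon = 0` gives the ideal gas).
#' @param tail Apply tail corrections (default `TRUE`).
#' @param init_density Starting density (defaults: solid 0.99, liquid 0.85).
#' @param max_displacement Translation cap.
#' @param max_dlnv Half-width of the `ln V` proposal.
#' @param n_blocks Error blocks.
#' @param virial_every Evaluate the virial pressure every this many sweeps.
#' @param scramble_sweeps Constant-volume melt sweeps before equilibration
#'   (defaults: solid 0, liquid 300).
#' @param scramble_temperature Temperature of the scramble stage.
#' @return A `thermo_state`: temperature, pressure, density / energy /
#'   enthalpy per particle with block standard errors, virial pressure,
#'   acceptance rates and the final configuration.
#' @export
run_npt <- function(phase = c("liquid", "fcc_solid"), n_particles,
                    temperature, pressure, cutoff = 4.75, sweeps = 10000,
                    equil = 2000, seed = 1, epsilon = 1, sigma = 1,
                    tail = TRUE, init_density = NULL,
                    max_displacement = 0.2, max_dlnv = 0.02, n_blocks = 5,
                    virial_every = 10, scramble_sweeps = NULL,
                    scramble_temperature = 1.5) {
  phase <- match.arg(phase)
  stopifnot(temperature > 0, pressure >= 0, cutoff > 0)
  solid <- phase == "fcc_solid"
  if (is.null(init_density)) init_density <- if (solid) 0.99 else 0.85
  if (is.null(scramble_sweeps)) scramble_sweeps <- if (solid) 0 else 300
  config <- fcc_box_config(n_particles, init_density, partial = !solid)
  if (config$box_length < 2 * cutoff)
    stop(sprintf(
      "box %.3f below twice the cutoff %.3f: reduce cutoff or enlarge N",
      config$box_length, cutoff))
  out <- cpp_run_npt(config$positions, config$box_length, temperature,
                     pressure, epsilon, sigma, cutoff, tail,
                     as.integer(scramble_sweeps), scramble_temperature,
                     as.integer(equil), as.integer(sweeps), max_displacement,
                     max_dlnv, as.integer(seed), as.integer(n_blocks),
                     as.integer(virial_every))
  if (out$volume_rejects_boxmin > 0.005 * (sweeps + equil))
    warning(sprintf(
      "%g volume proposals rejected at the box = 2*cutoff floor; the state point may be unreachable at this N and cutoff",
      out$volume_rejects_boxmin))
  bse <- function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2) return(NA_real_)
    sd(v) / sqrt(length(v))
  }
  structure(list(
    phase = phase, temperature = temperature, pressure = pressure,
    cutoff = cutoff, n_particles = n_particles,
    rho = mean(out$rho_blocks), rho_se = bse(out$rho_blocks),
    u = mean(out$u_blocks), u_se = bse(out$u_blocks),
    h = mean(out$h_blocks), h_se = bse(out$h_blocks),
    p_virial = mean(out$p_virial_blocks, na.rm = TRUE),
    p_virial_se = bse(out$p_virial_blocks),
    blocks = data.frame(rho = out$rho_blocks, u = out$u_blocks,
                        h = out$h_blocks, p_virial = out$p_virial_blocks),
    acc_translate = out$acc_translate, acc_volume = out$acc_volume,
    volume_rejects_boxmin = out$volume_rejects_boxmin,
    drift_warnings = out$drift_warnings,
    config = particle_config(out$xyz, box_length = out$box, mode = "bulk"),
    seed = seed, sweeps = sweeps, equil = equil),
    class = "thermo_state")
}

#' @export
print.thermo_state <- function(x, ...) {
  cat(sprintf(
    "thermo_state (%s): T = %g, P = %g\n  rho = %.5f +- %.5f, u/N = %.4f +- %.4f, h/N = %.4f +- %.4f\n",
    x$phase, x$temperature, x$pressure, x$rho, x$rho_se, x$u, x$u_se, x$h,
    x$h_se))
  invisible(x)
}

#' FCC nearest-neighbor spacing from bulk density
#'
#' For an FCC crystal of number density `rho`, the conventional cell edge
#' is `a = (4 / rho)^(1/3)` and the nearest-neighbor spacing is
#' `a / sqrt(2)`.
#'
#' @param rho Number density (> 0).
#' @return Nearest-neighbor spacing in sigma units.
#' @export
lattice_spacing_from_density <- function(rho) {
  stopifnot(rho > 0)
  (4 / rho)^(1 / 3) / sqrt(2)
}

#' @rdname lattice_spacing_from_density
#' @param spacing Nearest-neighbor spacing (> 0).
#' @export
density_from_spacing <- function(spacing) {
  stopifnot(spacing > 0)
  4 / (spacing * sqrt(2))^3
}
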