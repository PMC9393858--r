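#' Lennard-Jones pair potential specification
#'
#' Reduced-unit (epsilon = sigma = k_B = 1 by default) 12-6 Lennard-Jones
#' parameters. Cluster simulations use the full untruncated potential
#' (`cutoff = NULL`); bulk simulations truncate at `cutoff` and may add the
#' standard mean-field tail corrections.
#'
#' @param epsilon Energy scale (> 0).
#' @param sigma Length scale (> 0).
#' @param cutoff Optional pair-distance cutoff in units of `sigma`
#'   (must exceed `sigma`); `NULL` for no truncation.
#' @param tail_corrections Add analytical long-range corrections (bulk mode
#'   only; requires a cutoff).
#' @return An object of class `lj_spec`.
#' @export
lj_spec <- function(epsilon = 1, sigma = 1, cutoff = NULL,
                    tail_corrections = FALSE) {
  stopifnot(is.numeric(epsilon), length(epsilon) == 1, epsilon >= 0)
  stopifnot(is.numeric(sigma), length(sigma) == 1, sigma > 0)
  if (!is.null(cutoff)) {
    stopifnot(is.numeric(cutoff), length(cutoff) == 1)
    if (cutoff <= sigma) stop("cutoff must exceed sigma")
  }
  if (tail_corrections && is.null(cutoff))
    stop("tail corrections require a cutoff")
  structure(list(epsilon = epsilon, sigma = sigma, cutoff = cutoff,
                 tail_corrections = isTRUE(tail_corrections)),
            class = "lj_spec")
}

#' @export
print.lj_spec <- function(x, ...) {
  cat(sprintf("Lennard-Jones potential: epsilon = %g, sigma = %g, %s%s\n",
              x$epsilon, x$sigma,
              if (is.null(x$cutoff)) "no cutoff" else
                sprintf("cutoff = %g", x$cutoff),
              if (x$tail_corrections) ", tail corrections" else ""))
  invisible(x)
}

#' Particle configuration
#'
#' Holds particle coordinates either as an isolated cluster in open space
#' (`mode = "cluster"`) or in a periodic cubic box (`mode = "bulk"`). Bulk
#' coordinates are wrapped into `[0, box_length)`.
#'
#' @param positions Numeric matrix with 3 columns (sigma units); may have
#'   zero rows.
#' @param box_length Cubic box edge for bulk mode; must be `NULL` for
#'   cluster mode.
#' @param mode `"cluster"` or `"bulk"`.
#' @return An object of class `particle_config`.
#' @export
particle_config <- function(positions, box_length = NULL,
                            mode = c("cluster", "bulk")) {
  mode <- match.arg(mode)
  positions <- as.matrix(positions)
  if (length(positions) == 0) positions <- matrix(numeric(0), 0, 3)
  if (ncol(positions) != 3) stop("positions must have 3 columns")
  storage.mode(positions) <- "double"
  dimnames(positions) <- NULL
  if (mode == "bulk") {
    if (is.null(box_length) || box_length <= 0)
      stop("bulk mode requires a positive box_length")
    positions <- positions - box_length * floor(positions / box_length)
  } else if (!is.null(box_length)) {
    stop("cluster mode must not carry a box_length")
  }
  structure(list(positions = positions, box_length = box_length, mode = mode),
            class = "particle_config")
}

#' @export
print.particle_config <- function(x, ...) {
  cat(sprintf("particle_config: %d particles, %s mode%s\n",
              nrow(x$positions), x$mode,
              if (x$mode == "bulk") sprintf(", box %g", x$box_length) else ""))
  invisible(x)
}

#' Lennard-Jones pair energy
#'
#' u(r) = 4 epsilon \[(sigma/r)^12 - (sigma/r)^6\]; zero beyond the cutoff
#' when the specification carries one.
#'
#' @param r Pair distance(s), > 0.
#' @param spec An [lj_spec()].
#' @return Energy in reduced units (vectorized over `r`).
#' @export
pair_energy <- function(r, spec = lj_spec()) {
  if (any(r <= 0)) stop("pair distance must be positive")
  s6 <- (spec$sigma / r)^6
  e <- 4 * spec$epsilon * (s6^2 - s6)
  if (!is.null(spec$cutoff)) e[r > spec$cutoff] <- 0
  e
}

#' Total potential energy of a configuration
#'
#' Sum of pair energies over all unordered pairs. Bulk mode uses the
#' minimum-image convention and, if enabled, adds the analytical tail
#' correction `N * u_tail(rho, r_c)`.
#'
#' @param config A [particle_config()].
#' @param spec An [lj_spec()].
#' @return Total energy (reduced units).
#' @export
total_energy <- function(config, spec = lj_spec()) {
  n <- nrow(config$positions)
  if (n < 2) return(0)
  bulk <- config$mode == "bulk"
  if (bulk && !is.null(spec$cutoff) && config$box_length < 2 * spec$cutoff)
    stop("box_length must be at least twice the cutoff")
  e <- cpp_pair_sum_energy(config$positions, spec$epsilon, spec$sigma,
                           if (is.null(spec$cutoff)) -1 else spec$cutoff,
                           if (bulk) config$box_length else -1)
  if (bulk && spec$tail_corrections) {
    rho <- n / config$box_length^3
    e <- e + n * tail_correction(rho, spec$cutoff, spec)$energy
  }
  e
}

#' Incremental energy change of a single-particle move
#'
#' Energy difference for inserting, deleting or displacing one particle,
#' computed from only the pairs involving that particle (exact bookkeeping,
#' no full recompute).
#'
#' @param config A [particle_config()].
#' @param change One of `"insertion"`, `"deletion"`, `"displacement"`.
#' @param index Particle row index (deletion/displacement).
#' @param position New/inserted coordinates, length 3.
#' @param spec An [lj_spec()].
#' @return The energy difference `E(after) - E(before)`.
#' @export
delta_energy <- function(config, change = c("insertion", "deletion",
                                            "displacement"),
                         index = NULL, position = NULL, spec = lj_spec()) {
  change <- match.arg(change)
  n <- nrow(config$positions)
  box <- if (config$mode == "bulk") config$box_length else -1
  rc <- if (is.null(spec$cutoff)) -1 else spec$cutoff
  one <- function(pos, skip) {
    cpp_one_particle_energy(config$positions, as.numeric(pos), skip,
                            spec$epsilon, spec$sigma, rc, box)
  }
  if (change == "insertion") {
    if (is.null(position)) stop("insertion requires a position")
    return(one(position, -1L))
  }
  if (is.null(index) || index < 1 || index > n)
    stop("index out of range")
  if (change == "deletion")
    return(-one(config$positions[index, ], index - 1L))
  if (is.null(position)) stop("displacement requires a position")
  one(position, index - 1L) - one(config$positions[index, ], index - 1L)
}

#' Analytical long-range (tail) corrections
#'
#' Mean-field corrections for a homogeneous fluid truncated at `r_c`:
#' `u_tail = (8/3) pi rho eps sigma^3 [ (1/3)(sigma/r_c)^9 - (sigma/r_c)^3 ]`
#' per particle, and the matching pressure correction
#' `p_tail = (16/3) pi rho^2 eps sigma^3 [ (2/3)(sigma/r_c)^9 - (sigma/r_c)^3 ]`.
#'
#' @param density Number density rho (>= 0).
#' @param cutoff Truncation radius r_c (> 0).
#' @param spec An [lj_spec()].
#' @return List with `energy` (per particle) and `pressure` corrections.
#' @export
tail_correction <- function(density, cutoff, spec = lj_spec()) {
  stopifnot(density >= 0, cutoff > 0)
  sr3 <- (spec$sigma / cutoff)^3
  sr9 <- sr3^3
  list(energy = (8 / 3) * pi * density * spec$epsilon * spec$sigma^3 *
         (sr9 / 3 - sr3),
       pressure = (16 / 3) * pi * density^2 * spec$epsilon * spec$sigma^3 *
         (2 * sr9 / 3 - sr3))
}

#' Read an XYZ configuration file
#'
#' The comment line carries `mode=<cluster|bulk>` and, for bulk,
#' `box_length=<L>`; the element tag is "LJ".
#'
#' @param path File path.
#' @return A [particle_config()].
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  comment <- lines[2]
  mode <- if (grepl("mode=bulk", comment)) "bulk" else "cluster"
  box <- NULL
  if (mode == "bulk") {
    m <- regmatches(comment, regexec("box_length=([0-9.eE+-]+)", comment))[[1]]
    if (length(m) < 2) stop("bulk XYZ file lacks box_length")
    box <- as.numeric(m[2])
  }
  if (n == 0) return(particle_config(matrix(numeric(0), 0, 3), box, mode))
  body <- do.call(rbind, strsplit(trimws(lines[3:(2 + n)]), "[[:space:]]+"))
  pos <- matrix(as.numeric(body[, 2:4, drop = FALSE]), ncol = 3)
  particle_config(pos, box, mode)
}

#' Write an XYZ configuration file
#'
#' @param config A [particle_config()].
#' @param path File path.
#' @param digits Coordinate precision.
#' @return Invisibly, `path`.
#' @export
write_xyz <- function(config, path, digits = 10) {
  n <- nrow(config$positions)
  comment <- if (config$mode == "bulk")
    sprintf("mode=bulk box_length=%.*g", digits, config$box_length)
  else "mode=cluster"
  lines <- c(as.character(n), comment)
  if (n > 0) {
    fmt <- sprintf("LJ %%.%dg %%.%dg %%.%dg", digits, digits, digits)
    lines <- c(lines, sprintf(fmt, config$positions[, 1],
                              config$positions[, 2], config$positions[, 3]))
  }
  writeLines(lines, path)
  invisible(path)
}
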