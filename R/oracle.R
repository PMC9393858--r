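# Exact references for tiny grand-canonical lattice models. These certify
# the AVB acceptance rules: every connected occupancy pattern of a small
# site set has weight (n_v V_in)^n exp(-beta (E + eta(n))), with E either
# zero (ideal) or the LJ energy at site centers (frozen). The positional
# integral over each binding sphere factorizes to V_in exactly in both
# modes, so the pattern distribution is known in closed form.

#' Exact grand-canonical distribution of a tiny lattice model
#'
#' Enumerates every connected occupancy pattern of at most 12 given sites
#' and returns exact size and pattern probabilities.
#'
#' @param sites Site table (rows of [generate_sites()]); at most 12 rows.
#' @param lattice The [fcc_lattice()] the sites belong to.
#' @param reservoir A [reservoir_spec()].
#' @param params A [move_params()] (insertion volume).
#' @param energy_mode `"ideal"` or `"frozen"`.
#' @param spec An [lj_spec()] for frozen energies.
#' @param bias Optional [bias_potential()].
#' @param window Optional [size_window()] restricting sizes (defaults to
#'   1..number of sites).
#' @return List with `p_n` (data frame `n`, `p`), `patterns` (data frame
#'   `mask`, `n`, `p`; `mask` has bit q set when site row q+1 is occupied)
#'   and the insertion volume used.
#' @export
enumerate_lattice_gc <- function(sites, lattice, reservoir, params,
                                 energy_mode = c("ideal", "frozen"),
                                 spec = lj_spec(), bias = NULL,
                                 window = NULL) {
  energy_mode <- match.arg(energy_mode)
  s <- nrow(sites)
  if (s > 12) stop("enumeration is limited to 12 sites")
  if (is.null(window)) window <- size_window(1, s)
  tab <- .site_tables(lattice, sites = sites)
  pos <- tab$pos
  nbr <- tab$nbr
  pair_e <- matrix(0, s, s)
  if (energy_mode == "frozen" && s > 1) {
    d <- as.matrix(stats::dist(pos))
    pair_e <- ifelse(d > 0, 4 * spec$epsilon *
                       ((spec$sigma / pmax(d, 1e-300))^12 -
                          (spec$sigma / pmax(d, 1e-300))^6), 0)
    diag(pair_e) <- 0
  }
  adj <- matrix(FALSE, s, s)
  for (q in seq_len(s))
    for (m in 1:12)
      if (nbr[q, m] >= 0) adj[q, nbr[q, m] + 1] <- TRUE

  connected <- function(members) {
    if (length(members) <= 1) return(TRUE)
    seen <- logical(length(members))
    seen[1] <- TRUE
    stack <- 1L
    while (length(stack)) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      nxt <- which(adj[members[p], members] & !seen)
      seen[nxt] <- TRUE
      stack <- c(stack, nxt)
    }
    all(seen)
  }

  z <- reservoir$density * params$v_in
  masks <- integer(0)
  ns <- integer(0)
  wts <- numeric(0)
  for (mask in seq_len(2^s - 1)) {
    members <- which(bitwAnd(mask, bitwShiftL(1L, 0:(s - 1))) > 0)
    n <- length(members)
    if (n < window$n_min || n > window$n_max) next
    if (!connected(members)) next
    e <- if (n > 1) sum(pair_e[members, members]) / 2 else 0
    eta <- if (is.null(bias)) 0 else bias_value(bias, n)
    if (is.na(eta)) next
    wts <- c(wts, z^n * exp(-reservoir$beta * (e + eta)))
    masks <- c(masks, mask)
    ns <- c(ns, n)
  }
  if (!length(wts)) stop("no connected pattern satisfies the window")
  p <- wts / sum(wts)
  p_n <- vapply(sort(unique(ns)), function(k) sum(p[ns == k]), numeric(1))
  list(p_n = data.frame(n = sort(unique(ns)), p = p_n),
       patterns = data.frame(mask = masks, n = ns, p = p),
       v_in = params$v_in)
}

#' Compare the cluster MC engine to the exact enumeration
#'
#' Runs the real lattice-AVB engine on a tiny model and chi-square-tests
#' the visited size and pattern frequencies against
#' [enumerate_lattice_gc()]. Samples are thinned (`sample_every`) to tame
#' autocorrelation before the test.
#'
#' @inheritParams enumerate_lattice_gc
#' @param n_moves Move attempts.
#' @param seed Integer seed.
#' @param sample_every Thinning interval for recorded samples.
#' @param p_swap Swap-move probability (rest are intrasite jumps).
#' @param .drop_count_factor Corrupt the acceptance rule (negative
#'   control).
#' @return List with `p_size`, `p_pattern` (chi-square p-values),
#'   `observed_n`, `expected_n`, and the run outputs.
#' @export
mc_vs_oracle <- function(sites, lattice, reservoir, params, n_moves, seed,
                         energy_mode = c("ideal", "frozen"),
                         spec = lj_spec(), bias = NULL, window = NULL,
                         sample_every = 25, p_swap = 0.5,
                         .drop_count_factor = FALSE) {
  energy_mode <- match.arg(energy_mode)
  s <- nrow(sites)
  if (is.null(window)) window <- size_window(1, s)
  exact <- enumerate_lattice_gc(sites, lattice, reservoir, params,
                                energy_mode, spec, bias, window)
  # start from the most probable pattern of the smallest size
  cand <- exact$patterns[exact$patterns$n == min(exact$patterns$n), ]
  mask0 <- cand$mask[which.max(cand$p)]
  members <- which(bitwAnd(mask0, bitwShiftL(1L, 0:(s - 1))) > 0)
  tab <- .site_tables(lattice, sites = sites)
  state <- cluster_state(tab$pos[members, , drop = FALSE], "solid",
                         lattice = lattice,
                         site_ids = sites$id[members])
  eng <- list(site_pos = tab$pos, site_nbr = tab$nbr,
              occ0 = as.integer(members - 1L), sites = sites)
  run <- run_gc_cluster(state, reservoir, params, window, bias = bias,
                        n_moves = n_moves, seed = seed, p_swap = p_swap,
                        sample_every = sample_every,
                        energy_mode = energy_mode, spec = spec,
                        track_patterns = TRUE,
                        .drop_count_factor = .drop_count_factor,
                        .engine = eng)
  obs_n <- rowSums(run$histogram$counts)
  names(obs_n) <- run$histogram$n
  exp_n <- setNames(numeric(length(obs_n)), names(obs_n))
  exp_n[as.character(exact$p_n$n)] <- exact$p_n$p
  keep <- exp_n > 0
  p_size <- stats::chisq.test(obs_n[keep], p = exp_n[keep],
                              rescale.p = TRUE)$p.value
  # patterns: align observed counts onto the enumerated support
  obs_pat <- setNames(numeric(nrow(exact$patterns)),
                      as.character(exact$patterns$mask))
  got <- run$patterns
  if (!is.null(got)) {
    idx <- match(as.character(got$mask), names(obs_pat))
    ok <- !is.na(idx)
    obs_pat[idx[ok]] <- got$count[ok]
    off_support <- sum(got$count[!ok])
  } else {
    off_support <- NA_real_
  }
  p_pattern <- stats::chisq.test(obs_pat, p = exact$patterns$p,
                                 rescale.p = TRUE)$p.value
  list(p_size = p_size, p_pattern = p_pattern, observed_n = obs_n,
       expected_n = exp_n, off_support = off_support, run = run,
       exact = exact, seed = seed)
}
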