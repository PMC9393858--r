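#' Size-dependent bias potential
#'
#' Umbrella bias `eta(n)` over cluster sizes. Sizes outside the domain are
#' treated as excluded (infinite bias).
#'
#' @param n Integer cluster sizes.
#' @param eta Bias energies (reduced units), parallel to `n`; finite.
#' @return An object of class `bias_potential`.
#' @export
bias_potential <- function(n, eta) {
  stopifnot(length(n) == length(eta), all(is.finite(eta)))
  ord <- order(n)
  structure(data.frame(n = as.integer(n[ord]), eta = eta[ord]),
            class = c("bias_potential", "data.frame"))
}

#' Evaluate a bias potential
#'
#' @param bias A [bias_potential()] (or `NULL`, meaning zero bias).
#' @param n Sizes at which to evaluate.
#' @return `eta(n)`, `NA` outside the domain (`0` everywhere for `NULL`).
#' @export
bias_value <- function(bias, n) {
  if (is.null(bias)) return(rep(0, length(n)))
  bias$eta[match(n, bias$n)]
}

#' Visited-size histogram with error blocks
#'
#' @param n Integer sizes.
#' @param counts Matrix of nonnegative counts, one row per size and one
#'   column per block (a plain vector is treated as a single block).
#' @return An object of class `size_histogram`.
#' @export
size_histogram <- function(n, counts) {
  if (is.null(dim(counts))) counts <- matrix(counts, ncol = 1)
  stopifnot(nrow(counts) == length(n), all(counts >= 0))
  structure(list(n = as.integer(n), counts = counts),
            class = "size_histogram")
}

#' @export
print.size_histogram <- function(x, ...) {
  cat(sprintf("size_histogram: sizes %d..%d, %d blocks, %g samples\n",
              min(x$n), max(x$n), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Max/min sampling ratio of a histogram
#'
#' The evenness measure used to stop the self-adaptive bias iteration.
#'
#' @param hist A [size_histogram()].
#' @return `max(counts) / min(counts)` over total counts; `Inf` if any size
#'   was never visited.
#' @export
even_sampling_ratio <- function(hist) {
  tot <- rowSums(hist$counts)
  if (any(tot == 0)) return(Inf)
  max(tot) / min(tot)
}

#' Unbias a size histogram into a formation free-energy profile
#'
#' Removes the umbrella bias:
#' `beta dG(n) = -ln H(n) - beta eta(n) + C`, with the additive constant
#' fixed by the anchor. Per-block profiles give standard errors of the mean
#' across blocks.
#'
#' @param hist A [size_histogram()].
#' @param bias The [bias_potential()] used in the run (`NULL` = unbiased).
#' @param temperature Reduced temperature.
#' @param anchor Length-2 vector `c(n, value)` fixing `dG(anchor n) =
#'   value`; defaults to zero at the smallest visited size.
#' @param partial If `TRUE`, estimate from pooled counts over whichever
#'   sizes were visited (no block errors) instead of erroring on unvisited
#'   sizes; used inside the self-adaptive bias iteration.
#' @return A `free_energy_profile`: data frame `(n, delta_G, se)` with the
#'   per-block profiles in `attr(, "blocks")`.
#' @export
unbias <- function(hist, bias = NULL, temperature, anchor = NULL,
                   partial = FALSE) {
  stopifnot(temperature > 0)
  eta <- bias_value(bias, hist$n)
  eta[is.na(eta)] <- 0
  tot <- rowSums(hist$counts)
  if (partial) {
    keep <- tot > 0
    n <- hist$n[keep]
    g <- -temperature * log(tot[keep]) - eta[keep]
    n0 <- if (is.null(anchor)) n[1] else anchor[1]
    v0 <- if (is.null(anchor)) 0 else anchor[2]
    g <- g - g[match(n0, n)] + v0
    out <- data.frame(n = n, delta_G = g, se = NA_real_)
    attr(out, "temperature") <- temperature
    class(out) <- c("free_energy_profile", "data.frame")
    return(out)
  }
  if (any(hist$counts == 0)) {
    bad <- hist$n[which(apply(hist$counts == 0, 1, any))[1]]
    stop(sprintf("insufficient sampling: size %d unvisited in some block",
                 bad))
  }
  n0 <- if (is.null(anchor)) hist$n[1] else anchor[1]
  v0 <- if (is.null(anchor)) 0 else anchor[2]
  i0 <- match(n0, hist$n)
  if (is.na(i0)) stop("anchor size not inside the histogram domain")
  raw <- apply(hist$counts, 2, function(h) -temperature * log(h) - eta)
  blocks <- apply(raw, 2, function(g) g - g[i0] + v0)
  g_mean <- rowMeans(blocks)
  g_se <- apply(blocks, 1, sd) / sqrt(ncol(blocks))
  out <- data.frame(n = hist$n, delta_G = g_mean, se = g_se)
  attr(out, "blocks") <- blocks
  attr(out, "blocks_raw") <- raw  # pre-anchor: keeps increments exactly
                                  # anchor-independent, bit for bit
  attr(out, "temperature") <- temperature
  attr(out, "anchor") <- c(n = n0, value = v0)
  class(out) <- c("free_energy_profile", "data.frame")
  out
}

#' Per-particle free-energy increments
#'
#' Builds the series `(n, x, dG(n) - dG(n-1), se)` with
#' `x = n^(2/3) - (n-1)^(2/3)` for every size whose predecessor is also in
#' the profile. The additive anchor cancels exactly; errors come from the
#' scatter of per-block increments (or, without blocks, from quadrature of
#' the profile errors).
#'
#' @param profile A `free_energy_profile` from [unbias()].
#' @return A `delta_g_series`: data frame `(n, x, ddg, se)`.
#' @export
delta_g_series <- function(profile) {
  n <- profile$n
  keep <- which(match(n - 1L, n, nomatch = 0L) > 0L)
  if (!length(keep)) stop("profile contains no adjacent-size pairs")
  prev <- match(n[keep] - 1L, n)
  blocks <- attr(profile, "blocks_raw") %||% attr(profile, "blocks")
  if (!is.null(blocks)) {
    d <- blocks[keep, , drop = FALSE] - blocks[prev, , drop = FALSE]
    ddg <- rowMeans(d)
    se <- apply(d, 1, sd) / sqrt(ncol(d))
  } else {
    ddg <- profile$delta_G[keep] - profile$delta_G[prev]
    se <- sqrt(profile$se[keep]^2 + profile$se[prev]^2)
  }
  out <- data.frame(n = n[keep],
                    x = n[keep]^(2 / 3) - (n[keep] - 1)^(2 / 3),
                    ddg = ddg, se = se)
  class(out) <- c("delta_g_series", "data.frame")
  out
}

#' Self-adaptive bias update
#'
#' The next-iteration bias is the negative of the current free-energy
#' estimate, `eta_new(n) = -dG_est(n)`, so that a perfect estimate yields
#' even sampling. Sizes of the target window not covered by the profile are
#' filled by linear extrapolation of the edge slope (mean of up to three
#' edge increments), which lets the iteration reach initially unvisited
#' sizes.
#'
#' @param profile A `free_energy_profile`.
#' @param window Optional [size_window()] the bias must cover.
#' @return A [bias_potential()].
#' @export
adapt_bias <- function(profile, window = NULL) {
  stopifnot(all(is.finite(profile$delta_G)))
  n <- profile$n
  eta <- -profile$delta_G
  if (!is.null(window)) {
    lo <- window$n_min:window$n_max
    missing_lo <- setdiff(lo, n)
    if (length(missing_lo)) {
      edge_slope <- function(side) {
        if (length(n) < 2) return(0)
        d <- diff(eta[order(n)])
        k <- min(3, length(d))
        if (side == "low") mean(d[seq_len(k)]) else mean(d[seq(length(d) - k + 1, length(d))])
      }
      below <- missing_lo[missing_lo < min(n)]
      above <- missing_lo[missing_lo > max(n)]
      if (length(below)) {
        s <- edge_slope("low")
        eta <- c(eta[1] - s * (min(n) - below), eta)
        n <- c(below, n)
      }
      if (length(above)) {
        s <- edge_slope("high")
        eta <- c(eta, eta[length(eta)] + s * (above - max(n)))
        n <- c(n, above)
      }
      inside <- setdiff(missing_lo, c(below, above))
      if (length(inside)) {  # interior gaps: linear interpolation
        fill <- approx(n, eta, xout = inside)$y
        n <- c(n, inside)
        eta <- c(eta, fill)
      }
      keep <- n %in% lo
      n <- n[keep]
      eta <- eta[keep]
    }
  }
  bias_potential(n, eta)
}

#' Extend a bias to larger sizes with the CNT line
#'
#' Projects formation free energies beyond the sampled range using the
#' fitted line `ddG(m) = b + s (m^(2/3) - (m-1)^(2/3))` and returns the
#' flattening bias `eta(n) = -[dG(n_ref) + sum_(m=n_ref+1)^n ddG(m)]`.
#'
#' @param fit A `cnt_fit` from [fit_delta_g()].
#' @param n_ref Reference size (must be inside the fitted range's reach,
#'   i.e. not below its lower end).
#' @param g_ref `dG(n_ref)` from the sampled profile.
#' @param n_target Largest size to extend to (>= n_ref).
#' @return A [bias_potential()] over `n_ref..n_target`.
#' @export
cnt_extend_bias <- function(fit, n_ref, g_ref, n_target) {
  if (n_target < n_ref)
    stop("extension target below the reference size: extrapolating below ",
         "the fitted range is not allowed")
  n <- n_ref:n_target
  if (length(n) == 1) return(bias_potential(n, -g_ref))
  m <- n[-1]
  ddg <- fit$intercept + fit$slope * (m^(2 / 3) - (m - 1)^(2 / 3))
  bias_potential(n, -(g_ref + c(0, cumsum(ddg))))
}

#' Iterate the self-adaptive bias until sampling is even
#'
#' Alternates short biased runs with [unbias()] (partial mode) and
#' [adapt_bias()] until the max/min histogram ratio drops below
#' `target_ratio` (default 10) or `max_iter` iterations (default 20) are
#' spent.
#'
#' @inheritParams run_gc_cluster
#' @param moves_per_iter Move attempts per iteration.
#' @param max_iter Iteration cap.
#' @param target_ratio Evenness threshold on max/min visited counts.
#' @param initial_bias Starting bias (`NULL` = none).
#' @return List with the final `bias`, final `state`, `converged` flag, the
#'   per-iteration evenness `ratios`, and the last run's histogram.
#' @export
iterate_bias <- function(state, reservoir, params, window, seed,
                         moves_per_iter, max_iter = 20, target_ratio = 10,
                         initial_bias = NULL,
                         energy_mode = c("lj", "ideal", "frozen"),
                         spec = lj_spec(), p_swap = 0.5, sample_every = 1) {
  energy_mode <- match.arg(energy_mode)
  bias <- initial_bias
  ratios <- numeric(0)
  run <- NULL
  for (it in seq_len(max_iter)) {
    run <- run_gc_cluster(state, reservoir, params, window, bias = bias,
                          n_moves = moves_per_iter, seed = seed + it,
                          p_swap = p_swap, sample_every = sample_every,
                          energy_mode = energy_mode, spec = spec)
    state <- run$state
    ratios <- c(ratios, even_sampling_ratio(run$histogram))
    if (ratios[length(ratios)] < target_ratio)
      return(list(bias = bias, state = state, converged = TRUE,
                  ratios = ratios, histogram = run$histogram))
    prof <- unbias(run$histogram, bias, reservoir$temperature, partial = TRUE)
    bias <- adapt_bias(prof, window)
  }
  list(bias = bias, state = state, converged = FALSE, ratios = ratios,
       histogram = if (is.null(run)) NULL else run$histogram)
}

#' Stitch two overlapping free-energy profiles
#'
#' Aligns the second profile onto the first by the least-squares offset
#' over their shared sizes (at least two required) and averages the
#' overlap with inverse-variance weights.
#'
#' @param p1,p2 `free_energy_profile` objects.
#' @return A combined `free_energy_profile` (block structure dropped).
#' @export
stitch_profiles <- function(p1, p2) {
  shared <- intersect(p1$n, p2$n)
  if (length(shared) < 2)
    stop("profiles must overlap in at least two sizes")
  i1 <- match(shared, p1$n)
  i2 <- match(shared, p2$n)
  offset <- mean(p1$delta_G[i1] - p2$delta_G[i2])
  g2 <- p2$delta_G + offset
  all_n <- sort(union(p1$n, p2$n))
  g <- se <- numeric(length(all_n))
  for (q in seq_along(all_n)) {
    j1 <- match(all_n[q], p1$n)
    j2 <- match(all_n[q], p2$n)
    if (!is.na(j1) && !is.na(j2)) {
      w1 <- 1 / max(p1$se[j1], 1e-12)^2
      w2 <- 1 / max(p2$se[j2], 1e-12)^2
      g[q] <- (w1 * p1$delta_G[j1] + w2 * g2[j2]) / (w1 + w2)
      se[q] <- sqrt(1 / (w1 + w2))
    } else if (!is.na(j1)) {
      g[q] <- p1$delta_G[j1]
      se[q] <- p1$se[j1]
    } else {
      g[q] <- g2[j2]
      se[q] <- p2$se[j2]
    }
  }
  out <- data.frame(n = all_n, delta_G = g, se = se)
  attr(out, "temperature") <- attr(p1, "temperature")
  class(out) <- c("free_energy_profile", "data.frame")
  out
}
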