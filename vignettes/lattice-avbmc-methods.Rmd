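---
title: "Cluster Monte Carlo free energies for solid and liquid Lennard-Jones phases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster Monte Carlo free energies for solid and liquid Lennard-Jones phases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(avbmclj)
```

# The problem

Phase properties of solids — the chemical potential at coexistence, the
melting point, the triple point — are notoriously hard to extract from
molecular simulation. Standard routes (Einstein-crystal integration,
phase-switch Monte Carlo, interface-pinning, modified Gibbs-ensemble
setups) all work with bulk systems. This package implements a different
route: simulate *clusters* of the phase of interest in equilibrium with an
ideal-gas reservoir, measure how the cluster formation free energy grows
with size, and extrapolate to the bulk limit through the size dependence
that classical nucleation theory (CNT) prescribes.

For liquid clusters this is well-trodden ground: aggregation-volume-bias
(AVB) swap moves insert and delete particles directly inside a small
sphere around a cluster particle, so vapor-cluster exchange does not have
to wait for diffusion. The catch is that AVB-grown clusters are liquid
even far below the melting temperature — crystallization inside a cluster
has a barrier of tens of k_BT and simply never happens on simulation time
scales. The lattice-based AVB variant implemented here removes that
obstacle by construction: insertions are targeted at vacant
face-centered-cubic (FCC) lattice sites adjacent to the target particle's
site, every particle stays bound within a radius `r` of its own site, and
the cluster is therefore solid-like at every size from the start.

Everything is in reduced Lennard-Jones units (epsilon = sigma = k_B = 1).

# Sampling model

## Grand-canonical cluster ensemble

A cluster of `n` particles is coupled to an ideal-gas reservoir at number
density `n_v` and temperature `T`; the reservoir chemical potential
convention is `beta mu_gas = ln(n_v)` (kinetic term excluded, so `n_v = 1`
means `mu_gas = 0`). Cluster energies use the full untruncated LJ
potential (all pairs, open boundary). The sampled distribution is

    pi(state) ~ exp(-beta [U + eta(n)])

restricted to a size window `[n_min, n_max]`; `eta(n)` is an umbrella bias
over cluster size. Windows have hard reflecting bounds (out-of-window
proposals are rejected); since the analysis below only ever uses
adjacent-size ratios, windows do not distort anything.

## Moves

*Liquid clusters* (`original_avbmc_swap`, `translate_move`): the cluster
is defined by the Stillinger criterion — particles closer than `R` are
connected, the cluster is the connected component, and `R` also bounds the
insertion sphere around the target particle (`V_in = (4/3) pi R^3`).
Half the moves are swaps, half are translations capped at 0.2.

*Solid clusters* (`lattice_avbmc_swap`, `intrasite_jump`): every particle
is assigned to a distinct FCC site; two particles are neighbors when their
sites are adjacent (12-coordination), and each particle must stay within
`r` of its site. Insertions place a particle uniformly inside the sphere
of radius `r` around a vacant site adjacent to the target's site;
deletions remove an occupied neighbor. Intrasite jumps redraw a particle's
position uniformly inside its own binding sphere and are accepted with the
bare Boltzmann factor; they can never violate the binding condition. Swap
and jump moves are mixed 50/50. The lattice replicates on demand as the
cluster grows, is anchored in space, and sites carry ids stable under
extension.

## Acceptance rules

The acceptance probabilities are built per proposal path from detailed
balance, with all counts evaluated in the pre-move state
(`acceptance_argument()` documents all four variants):

    lattice insert:  min{1, n_v V_in e^(-beta dE) N N_vac / [(N+1)(N_in+1)]}
    lattice delete:  min{1, e^(-beta dE)/(n_v V_in) N N_in / [(N-1)(N_vac+1)]}
    original insert: min{1, n_v V_in e^(-beta dE) N / [(N+1)(N_in+1)]}
    original delete: min{1, e^(-beta dE)/(n_v V_in) N N_in / (N-1)}

with `dE` including the bias increment. Rather than trusting the algebra,
the package ships an exact enumeration oracle
(`enumerate_lattice_gc()`, `mc_vs_oracle()`): on models of at most 12
sites every connected occupancy pattern has weight
`(n_v V_in)^n exp(-beta (E + eta(n)))` — the positional integral over each
binding sphere factorizes to `V_in` exactly when energies are evaluated at
site centers ("frozen" mode) or are zero ("ideal" mode) — and the engine's
visited pattern frequencies are chi-square-tested against the exact
distribution. A deliberately corrupted rule (dropping the `N_vac`
counting factor) fails this test at p < 1e-6, so the oracle genuinely
discriminates. One consequence worth spelling out: in the ideal-gas dimer
the stationary ratio is `P(2)/P(1) = n_v V_in / 2`, the mass-action value
with the pair symmetry factor; the same factor appears in the two-site
lattice enumeration (two monomer patterns, one dimer pattern). The
`N/(N+1)`-type factors in the rules are exactly what makes the sampled
distribution consistent with the standard indistinguishable-particle
convention, which in turn is what makes the extrapolated intercept a bulk
chemical potential comparable to Gibbs-ensemble values.

# Free-energy analysis

`unbias()` converts a visited-size histogram under bias `eta` to

    beta dG(n) = -ln H(n) - beta eta(n) + C,

anchored at `dG(n0) = 0` for the smallest visited size (only differences
ever enter downstream results, so the additive convention is
inconsequential; the anchor-independence of the increments is exact and
tested). Runs are split into 5 blocks and all errors are standard errors
of the mean across blocks.

`adapt_bias()` implements the self-adaptive umbrella iteration: the next
bias is the negative of the current free-energy estimate, with linear
extrapolation of the edge slope into not-yet-visited sizes (that
extrapolation is this package's choice — without it a strongly downhill
window would never be climbed; convergence is declared when the max/min
visited-count ratio drops below 10, capped at 20 iterations, both
implementation choices). `cnt_extend_bias()` projects the bias to much
larger sizes along the fitted CNT line.

CNT decomposes the formation free energy into a bulk and a surface term,
`dG(n) = a n + b n^(2/3)`, so the per-particle increment
`ddG(n) = dG(n) - dG(n-1)` is linear in `x = n^(2/3) - (n-1)^(2/3)`:

* the intercept is the chemical potential difference between the infinite
  cluster (bulk phase) and the reservoir gas — at `n_v = 1`,
  `mu_bulk = intercept`;
* the slope is `s = (36 pi / rho^2)^(1/3) gamma` with `rho` the bulk
  density, giving the surface tension `gamma`.

`fit_delta_g()` fits this line by inverse-variance-weighted least squares;
parameter errors use the unscaled covariance `(X'WX)^(-1)` because the
block errors are taken at face value (500-replicate simulations confirm
68% one-sigma coverage). An unweighted fallback exists
(`weighted = FALSE`) since the choice is not dictated by the method.

# Bulk reference simulations

`run_npt()` is an isobaric-isothermal Metropolis sampler (864 particles by
default, spherical cutoff 4.75 sigma, analytical tail corrections for
energy and virial, one ln-V volume move per sweep with the `(N+1) ln V`
Jacobian). It supplies three inputs to the cluster analysis:

* the FCC nearest-neighbor spacing of the solid,
  `a_nn = (4/rho)^(1/3)/sqrt(2)`, evaluated at the saturated vapor
  pressure (1.128 at T = 0.6; the result is insensitive to the exact
  pressure anywhere in [0, 0.01]);
* the bulk liquid density entering the surface-tension conversion;
* enthalpies per particle `h = U/N + P/rho` for the Gibbs-Helmholtz
  propagation.

Volume proposals that would shrink the box below twice the cutoff are
rejected outright — the minimum-image convention would silently break
otherwise; with 864 particles at solid densities this is a ~5-sigma
fluctuation and the rejection count is reported. Liquid runs start from
an FCC lattice melted by a short constant-volume stage at T = 1.5 (300
sweeps); solid runs start from the perfect lattice at density 0.99.
Equilibration lengths and move caps (displacement 0.2, ln-V half-width
0.02) are recorded in every result object.

The saturated vapor pressure itself comes from a small two-parameter
Clausius-Clapeyron correlation `ln p = 3.3081 - 6.9514/T`
(`lj_saturation_pressure()`), anchored through the near-ideal saturated
vapor (`beta mu_liq = ln rho_v`, `p ~ rho_v T`) at the saturated-liquid
chemical potentials of the full LJ fluid at T = 0.6 and 0.7. It is meant
only for 0.55-0.80; the shipped liquid-vapor coexistence table
(`inst/extdata/lj_lv_coexistence_synthetic.tsv`, labelled synthetic
because it is generated from this correlation rather than taken from any
simulation campaign) is the default LV curve for triple-point location,
and any user-supplied (T, P) TSV can replace it.

# Phase diagram

With the bulk chemical potentials of liquid and solid at a common
reference temperature (the CNT intercepts at T = 0.6) and enthalpy tables
from NPT runs, `gibbs_helmholtz_mu()` propagates `beta mu` in temperature
by trapezoidal quadrature of `h(beta)` (step <= 0.001 in beta, linear
interpolation of `h` in beta, linear end-slope extrapolation just outside
the table). `melting_point()` bisects the chemical-potential crossing to
1e-6 in T and resamples the inputs from their stated errors (>= 1000
draws) for the uncertainty. `clapeyron_curve()` traces the solid-liquid
line `dP/dT = dh/(T dv)` by fourth-order Runge-Kutta (step <= 5e-4); by
default `dh` and `dv` are held at their melting-point values, which is
adequate because the traced interval to the LV crossing is of order 1e-4
in T (a re-evaluating mode accepts functions of (T, P)).
`triple_point()` intersects the SL and LV curves by monotone interpolation
and root bracketing. Because the SL line is steep (dP/dT ~ 10) and the LV
line nearly flat at these conditions, the triple point lands a fraction of
a millikelvin-equivalent above the melting temperature, reproducing the
qualitative structure of the reference calculation.

# Structure diagnostics

`coordination_histogram()` (neighbor cutoff 1.5 by default — the first
minimum region of the LJ pair correlation function; every report names the
cutoff used) classifies particles with fewer than 9 neighbors as surface
particles; for compact FCC balls of 100-1000 particles the surface count
scales with `n^(2/3)` to within ~30%. `q6_global()` computes the
Steinhardt bond-orientational order parameter with the *global* bond
average (all neighbor bonds pooled before the rotational invariant is
formed); the per-particle-averaged variant differs numerically and is
deliberately not used. For the ideal FCC bond set Q6 = 0.574524; random
bond sets decay like `N_bonds^(-1/2)`. `site_displacement_histogram()`
bins each particle's distance from its assigned site at 0.005; in the
bulk solid at T = 0.6 the mode sits near 0.1, which is also why binding
radii well below ~0.25 describe a different, over-constrained solid and
why `r` in the 0.25-0.5 range is the physically meaningful regime.

# Numerical choices and degenerate inputs

* Strict inequalities: Stillinger connectivity uses `d < R`; site binding
  uses `d <= r`. The boundary has measure zero; fixing the convention
  keeps runs deterministic.
* Insertion points are drawn uniformly in the sphere by radius-cubed
  inversion, so `V_in` is exactly `(4/3) pi radius^3`.
* The RNG is a single 64-bit Mersenne stream per run with the seed
  recorded in every output; raw 53-bit mantissa mapping keeps runs
  bit-identical across platforms. Identical seeds reproduce histograms
  and final configurations bit-for-bit.
* A running energy cache is resynchronized against a full recompute every
  1e5 moves; a drift above 1e-7 raises a warning (none observed in the
  test suite; typical drift is ~1e-14).
* Deletions from `n = n_min`, insertions with no vacant neighbor site,
  deletions of isolated particles, and criterion-breaking residuals are
  all auto-rejected and counted as attempts.
* Nearest-site ties in audits break to the lowest site id; assignments
  are carried through moves, never recomputed.
* `unbias()` refuses profiles with unvisited sizes (naming the size); the
  partial mode used inside the bias iteration pools blocks instead.

# What the tests do and do not show

The suite certifies the pieces that can be certified exactly: acceptance
rules against enumeration, incremental against recomputed energies
(<= 1e-9 relative), anchor independence (exact), closed-form
thermodynamic propagation (<= 1e-8), the ideal-FCC Q6 value (1e-4), and
calibration of the fit errors. The physical campaigns in the acceptance
tests are deliberately reduced: NPT runs use 2000-10000 production sweeps
(the reference calculation is insensitive at the 1e-3 level by then), and
the cluster acceptance-rate measurements use 1e6-2e6 move attempts in a
single window around n = 100, against >= 1e10 samples per cluster and
sizes up to 8000 in the reference work. Consequently the package
reproduces densities and the lattice spacing to ~1%, and swap acceptance
rates to within a couple of percentage points — but it does not attempt
the full delta-dG campaign across 100-8000-particle clusters on desk
hardware; the machinery (sparse windows, CNT bias extension, block
errors) is all present and exercised on small windows.

# Known limitations

* FCC only; extending to HCP/BCC would need new site tables but no new
  ideas.
* The lattice frame is fixed in space; the binding constraint pins the
  cluster, and no lattice translation/rotation moves are attempted.
* Surface properties of solid clusters inherit the sensitivity to `r`
  discussed above: the outer layer of a real solid cluster is liquid-like
  and a tight binding radius suppresses that physics.
* No configurational-bias machinery for molecular species; single-site LJ
  particles only.
* The reservoir is strictly ideal (no explicit vapor box).

# Problem sizes used by the shipped campaigns

The acceptance script runs, per seed: three 864-particle NPT campaigns
(10000/6000/6000 production sweeps), two cluster campaigns of 2e6 move
attempts in the window 90-110 after self-adaptive bias convergence, and
one closed-form evaluation. These sizes are this package's choice of a
reproducible desk-scale experiment; all are parameters, not constants.
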