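#' Saturated vapor pressure of the Lennard-Jones fluid
#'
#' Two-parameter Clausius-Clapeyron correlation
#' `ln p = 3.3081 - 6.9514 / T` for the full (tail-corrected) LJ fluid,
#' anchored through the near-ideal saturated vapor: at coexistence
#' `beta mu_liq = ln rho_v` and `p ~ rho_v T`, with the saturated-liquid
#' chemical potentials at T = 0.6 and T = 0.7 as anchor points. Intended
#' for the narrow range 0.55 <= T <= 0.80 around the triple point; the
#' bulk NPT results in this package are insensitive to the exact value
#' (densities shift by under 1e-4 across P in [0, 0.01]).
#'
#' @param temperature Reduced temperature(s).
#' @return Saturation pressure(s) in reduced units.
#' @export
lj_saturation_pressure <- function(temperature) {
  stopifnot(all(temperature > 0))
  if (any(temperature < 0.5 | temperature > 0.85))
    warning("correlation is calibrated for 0.55 <= T <= 0.80")
  exp(3.3081 - 6.9514 / temperature)
}
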