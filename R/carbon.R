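#' Water-limited light-saturated photosynthesis rate
#'
#' Harris-type response of the light-saturated photosynthesis rate to leaf
#' water potential: P_max = P_max0 (1 - exp(B_h (A_h + 1/psi))), clamped at
#' zero (the raw expression turns negative below psi = -1/A_h, where
#' photosynthesis shuts down).
#'
#' @param psi_leaf leaf water potential, MPa (< 0).
#' @param params photosynthesis parameter block (\code{P_max0}, \code{A_h},
#'   \code{B_h}).
#' @return light-saturated rate, mmol CO2 m-2 s-1 (vectorized).
#' @examples
#' pmax_water_limited(-1.949)  # ~61% of the unstressed maximum
#' @export
pmax_water_limited <- function(psi_leaf,
                               params = default_params()$photosynthesis) {
  if (any(psi_leaf >= 0)) stop("leaf water potential must be negative")
  params$P_max0 * pmax(0, 1 - exp(params$B_h * (params$A_h + 1 / psi_leaf)))
}

#' Gross carbon assimilation of a fruiting unit over one hour
#'
#' Saturating light response P(PAR) = P_max (1 - exp(-alpha PAR / P_max))
#' applied separately to the sunlit and shaded leaf pools, converted to
#' grams of carbon per hour.
#'
#' @param area_sun,area_shade leaf areas, m2.
#' @param par_sun,par_shade incident PAR on each pool, umol m-2 s-1.
#' @param p_max light-saturated rate, mmol CO2 m-2 s-1 (0 gives 0).
#' @param alpha quantum efficiency, mol CO2 mol photon-1.
#' @return gross assimilation, g C per unit per hour (vectorized).
#' @export
fu_assimilation <- function(area_sun, area_shade, par_sun, par_shade,
                            p_max, alpha = default_params()$photosynthesis$alpha) {
  if (any(area_sun < 0) || any(area_shade < 0)) stop("negative leaf area")
  rate <- function(par) {   # mmol CO2 m-2 s-1
    ifelse(p_max > 0,
           p_max * (1 - exp(-alpha * pmax(par, 0) * 1e-3 / pmax(p_max, 1e-12))),
           0)
  }
  mmol_s <- rate(par_sun) * area_sun + rate(par_shade) * area_shade
  mmol_s * 1e-3 * physical_constants()$carbon_molar_mass * 3600
}

#' Maintenance respiration of a compartment over one hour
#'
#' Q10 temperature response around a reference temperature; coefficients are
#' per day and converted to the hourly step here.
#'
#' @param dm compartment dry mass, g (>= 0).
#' @param t_air air temperature, degC (vector of hourly values allowed;
#'   the result sums over them).
#' @param coef maintenance coefficient, g C (g DM)-1 day-1 at \code{t_ref}.
#' @param q10 Q10 factor.
#' @param t_ref reference temperature, degC.
#' @return maintenance respiration, g C, summed over the supplied hours.
#' @export
maintenance_respiration <- function(dm, t_air, coef, q10 = 2, t_ref = 20) {
  if (any(dm < 0)) stop("negative dry mass")
  sum(coef * dm * q10^((t_air - t_ref) / 10) / 24)
}
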