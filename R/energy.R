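#' Jarvis multiplicative stomatal conductance
#'
#' g_s = gs_max f1(PAR) f2(VPD) f3(T_leaf) f4(psi_leaf). The parameters are
#' the fitted slope/offset pairs; the bounded sub-function forms are
#' \itemize{
#'   \item f1 = 1 - exp(-a_par PAR)
#'   \item f2 = 1 / (1 + exp(a_vpd VPD - b_vpd))
#'   \item f3 = 1 / (1 + exp(-a_temp (T - b_temp)))
#'   \item f4 = 1 / (1 + exp(a_psi psi - b_psi))
#' }
#' each clamped to [0, 1] (monotone bounded reconstructions; the parameter
#' pairs, not the forms, come from field calibration).
#'
#' @param par incident PAR, umol m-2 s-1.
#' @param vpd leaf-to-air vapour pressure deficit, hPa (>= 0).
#' @param t_leaf leaf temperature, degC.
#' @param psi_leaf leaf water potential, MPa.
#' @param params stomatal parameter block (see \code{default_params()$stomatal}).
#' @return stomatal conductance, mol m-2 s-1 (vectorized).
#' @examples
#' stomatal_conductance(1500, 10, 30, -0.5, default_params()$stomatal)
#' @export
stomatal_conductance <- function(par, vpd, t_leaf, psi_leaf,
                                 params = default_params()$stomatal) {
  clamp01 <- function(x) pmin(1, pmax(0, x))
  f1 <- clamp01(1 - exp(-params$a_par * pmax(par, 0)))
  f2 <- clamp01(1 / (1 + exp(params$a_vpd * pmax(vpd, 0) - params$b_vpd)))
  f3 <- clamp01(1 / (1 + exp(-params$a_temp * (t_leaf - params$b_temp))))
  f4 <- clamp01(1 / (1 + exp(params$a_psi * psi_leaf - params$b_psi)))
  params$gs_max * f1 * f2 * f3 * f4
}

#' Leaf boundary-layer conductance
#'
#' Sum of a forced flat-plate component scaling with sqrt(wind / leaf
#' dimension) and a free-convection component driven by the leaf-air
#' temperature difference, with a configurable floor for still air.
#'
#' @param wind wind speed, m s-1 (>= 0).
#' @param leaf_dim characteristic leaf dimension, m (> 0).
#' @param dT leaf minus air temperature, degC (free convection uses its
#'   positive part).
#' @param params boundary-layer parameter block.
#' @return boundary conductance, mol m-2 s-1 (vectorized).
#' @export
boundary_conductance <- function(wind, leaf_dim = NULL, dT = 0,
                                 params = default_params()$boundary_layer) {
  if (is.null(leaf_dim)) leaf_dim <- params$leaf_dim
  if (any(leaf_dim <= 0)) stop("leaf dimension must be positive")
  forced <- params$forced_coef * sqrt(pmax(wind, 0) / leaf_dim)
  free <- params$free_coef * (pmax(dT, 0) / leaf_dim)^0.25
  pmax(forced + free, params$floor)
}

# latent heat flux (W) of a leaf pool: hypostomatous, series gs-gb
latent_flux <- function(area, gs, gb, t_leaf_C, t_air_C, rh) {
  pc <- physical_constants()
  gtot <- ifelse(gs > 0 & gb > 0, 1 / (1 / gs + 1 / gb), 0)
  ea <- saturation_vp(t_air_C) * rh / 100
  vpd_leaf <- pmax(saturation_vp(t_leaf_C) - ea, 0)
  pc$lambda_mol * area * gtot * vpd_leaf / pc$p_atm
}

# sensible heat flux (W), two-sided exchange
sensible_flux <- function(area, gb, t_leaf_C, t_air_C) {
  pc <- physical_constants()
  2 * area * gb * pc$cp_mol * (t_leaf_C - t_air_C)
}

#' Solve the leaf energy balance of one or more leaf pools
#'
#' Finds the leaf temperature at which net radiation equals the sum of
#' sensible and latent heat fluxes, with stomatal conductance re-evaluated at
#' the candidate leaf temperature (leaf water potential held fixed). Solved
#' by a safeguarded Newton iteration on the residual, vectorized over pools;
#' any pool whose Newton step leaves the physical bracket (air temperature
#' +/- 20 degC) falls back to bisection.
#'
#' @param sw_abs absorbed shortwave (PAR + NIR), W, per pool.
#' @param area leaf area per pool, m2.
#' @param par incident PAR per pool, umol m-2 s-1 (for g_s).
#' @param t_air air temperature, degC.
#' @param rh relative humidity, percent.
#' @param wind wind speed, m s-1.
#' @param psi_leaf leaf water potential per pool, MPa (fixed here).
#' @param t_soil soil temperature, degC (defaults to air temperature).
#' @param t_env surrounding foliage temperature, degC (defaults to air).
#' @param params full parameter set.
#' @param gs_scale multiplier on stomatal conductance (0 closes stomata).
#' @param t_init optional initial leaf temperatures (warm start).
#' @param sky_emiss apparent sky emissivity override (computed from air
#'   temperature and humidity when NULL).
#' @return list with per-pool \code{t_leaf} (degC), \code{latent},
#'   \code{sensible}, \code{rn} (W), \code{gs}, \code{gb} (mol m-2 s-1),
#'   \code{E} (transpiration, mol s-1) and \code{resid} (W).
#' @export
solve_leaf_energy_balance <- function(sw_abs, area, par, t_air, rh, wind,
                                      psi_leaf, t_soil = t_air, t_env = t_air,
                                      params = default_params(),
                                      gs_scale = 1, t_init = NULL,
                                      sky_emiss = NULL) {
  n <- length(sw_abs)
  stopifnot(length(area) == n)
  pc <- physical_constants()
  eps_sky <- if (is.null(sky_emiss)) sky_emissivity(t_air, rh) else sky_emiss
  tir <- thermal_exchange(area, t_env + 273.15, t_air + 273.15,
                          t_soil + 273.15, eps_sky,
                          leaf_emiss = params$radiation$leaf_emissivity,
                          soil_emiss = params$radiation$soil_emissivity)
  ea <- saturation_vp(t_air) * rh / 100
  bl <- params$boundary_layer
  st <- params$stomatal
  gb_forced <- bl$forced_coef * sqrt(max(wind, 0) / bl$leaf_dim)
  two_sig_a <- 2 * pc$sigma * area
  le_coef <- pc$lambda_mol * area / pc$p_atm
  se_coef <- 2 * area * pc$cp_mol
  # Jarvis factors independent of leaf temperature
  f1 <- 1 - exp(-st$a_par * par * (par > 0))
  f4 <- 1 / (1 + exp(st$a_psi * psi_leaf - st$b_psi))
  gs_const <- gs_scale * st$gs_max * f1 * f4
  # residual of the energy balance at leaf temperature tl (all inputs
  # hoisted; this closure replicates stomatal_conductance/latent/sensible)
  resid_only <- function(tl) {
    dT <- tl - t_air
    dTp <- dT * (dT > 0)
    gb <- gb_forced + bl$free_coef * (dTp / bl$leaf_dim)^0.25
    gb <- gb + (bl$floor - gb) * (gb < bl$floor)
    vpd_leaf <- saturation_vp(tl) - ea
    vpd_leaf <- vpd_leaf * (vpd_leaf > 0)
    gs <- gs_const / ((1 + exp(st$a_vpd * vpd_leaf - st$b_vpd)) *
                        (1 + exp(-st$a_temp * (tl - st$b_temp))))
    gtot <- gs * gb / (gs + gb + 1e-300)
    sw_abs + tir - two_sig_a * (tl + 273.15)^4 -
      se_coef * gb * dT - le_coef * gtot * vpd_leaf
  }
  # analytic residual slope (the dominant terms; boundary-layer and
  # stomatal temperature sensitivities are left to the safeguard)
  slope_fn <- function(tl, gb, gtot) {
    des <- saturation_vp(tl) * 17.269 * 237.3 / (tl + 237.3)^2
    -(4 * two_sig_a * (tl + 273.15)^3 + se_coef * gb + le_coef * gtot * des)
  }
  lo <- rep(t_air - 20, n); hi <- rep(t_air + 20, n)
  tl <- if (is.null(t_init)) rep(t_air, n) else pmin(pmax(t_init, lo), hi)
  tol <- params$solver$resid_tol
  live <- area > 1e-12
  converged <- FALSE
  for (it in 1:60) {
    r <- resid_only(tl)
    up <- r > 0                   # residual decreases in T: root is above
    lo[up] <- tl[up]; hi[!up] <- tl[!up]
    if (all(abs(r[live]) < tol)) { converged <- TRUE; break }
    dT <- tl - t_air
    gb <- gb_forced + bl$free_coef * (dT * (dT > 0) / bl$leaf_dim)^0.25
    gb <- gb + (bl$floor - gb) * (gb < bl$floor)
    vpd_leaf <- saturation_vp(tl) - ea
    vpd_leaf <- vpd_leaf * (vpd_leaf > 0)
    gs <- gs_const / ((1 + exp(st$a_vpd * vpd_leaf - st$b_vpd)) *
                        (1 + exp(-st$a_temp * (tl - st$b_temp))))
    gtot <- gs * gb / (gs + gb + 1e-300)
    step <- -r / slope_fn(tl, gb, gtot)
    step[!is.finite(step)] <- 0
    step[step > 5] <- 5; step[step < -5] <- -5
    tln <- tl + step
    oob <- tln <= lo | tln >= hi | step == 0
    tln[oob] <- (lo[oob] + hi[oob]) / 2
    tl <- tln
  }
  if (!converged) {
    r <- resid_only(rep(t_air - 20, n)); r2 <- resid_only(rep(t_air + 20, n))
    bad <- which((r < 0 | r2 > 0) & live)[1]
    if (!is.na(bad))
      stop(sprintf(paste0("no root in bracket for pool %d: residual %.3f W ",
                          "at %.1f degC and %.3f W at %.1f degC"),
                   bad, r[bad], t_air - 20, r2[bad], t_air + 20))
    stop("leaf energy balance did not converge")
  }
  tl[!live] <- t_air
  # full fluxes at the solution
  dT <- tl - t_air
  gb <- gb_forced + bl$free_coef * (dT * (dT > 0) / bl$leaf_dim)^0.25
  gb <- gb + (bl$floor - gb) * (gb < bl$floor)
  vpd_leaf <- saturation_vp(tl) - ea
  vpd_leaf <- vpd_leaf * (vpd_leaf > 0)
  gs <- gs_const / ((1 + exp(st$a_vpd * vpd_leaf - st$b_vpd)) *
                      (1 + exp(-st$a_temp * (tl - st$b_temp))))
  gtot <- gs * gb / (gs + gb + 1e-300)
  le <- le_coef * gtot * vpd_leaf
  se <- se_coef * gb * dT
  rn <- sw_abs + tir - two_sig_a * (tl + 273.15)^4
  list(t_leaf = tl, latent = le, sensible = se, rn = rn,
       gs = gs, gb = gb, E = le / pc$lambda_mol, resid = rn - se - le)
}
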