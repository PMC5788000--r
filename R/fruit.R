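#' Stone/flesh partition of fruit dry mass
#'
#' The stone takes assimilates following a saturating curve of total fruit
#' dry mass; the flesh gets the remainder.
#'
#' @param dm total fruit dry mass, g (>= 0, vectorized).
#' @param params fruit block (\code{fs_sat}, \code{fs_slope}).
#' @return list with \code{stone} and \code{flesh} dry masses, g.
#' @examples
#' stone_flesh_partition(10)
#' @export
stone_flesh_partition <- function(dm, params = default_params()$fruit) {
  if (any(dm < 0)) stop("negative dry mass")
  stone <- params$fs_sat * (1 - exp(-params$fs_slope * dm))
  stone <- pmin(stone, dm)
  list(stone = stone, flesh = dm - stone)
}

#' Fruit skin transpiration
#'
#' Vapour loss through the fruit skin, proportional to fruit surface area
#' (allometric in fresh mass) and air vapour pressure deficit.
#'
#' @param fm fruit fresh mass, g (>= 0).
#' @param vpd air vapour pressure deficit, hPa (>= 0).
#' @param params fruit block (\code{transp_coef}, \code{surf_coef},
#'   \code{surf_exp}).
#' @return transpiration, g water h-1 (vectorized).
#' @export
fruit_transpiration <- function(fm, vpd, params = default_params()$fruit) {
  if (any(fm < 0) || any(vpd < 0)) stop("negative fresh mass or VPD")
  area <- params$surf_coef * fm^params$surf_exp     # cm2
  params$transp_coef * area * vpd
}

#' Osmotic pressure of the fruit flesh sap
#'
#' Van't Hoff relation over the four soluble sugars (carbon pools converted
#' to sugar mass, then to molar concentration in the flesh water) plus a
#' configurable constant for the other osmolytes.
#'
#' @param pools named vector or list of sugar carbon pools
#'   (\code{sucrose}, \code{sorbitol}, \code{glucose}, \code{fructose}), g C.
#' @param water_volume flesh water volume, L (> 0).
#' @param temp_K temperature, K.
#' @param params sugar block (for the carbon fractions).
#' @param pi_other constant contribution of non-sugar osmolytes, MPa.
#' @return osmotic pressure, MPa.
#' @export
osmotic_pressure <- function(pools, water_volume, temp_K = 293.15,
                             params = default_params()$sugar,
                             pi_other = 0) {
  if (any(water_volume <= 0)) stop("water volume must be positive")
  mw <- c(sucrose = 342.30, sorbitol = 182.17,
          glucose = 180.16, fructose = 180.16)
  conc <- 0
  for (s in names(mw)) {
    mass <- pools[[s]] / params$cf[[s]]             # g sugar
    conc <- conc + mass / mw[[s]] / water_volume    # mol L-1
  }
  physical_constants()$R_MPa * temp_K * conc + pi_other
}

# quasi-steady turgor: root of inflow(P) - V*phi*max(0, P - Y) with
# inflow(P) = aL_fm * (psi_stem - P + pi_f) - transp; piecewise linear,
# strictly decreasing in P, so the root is closed-form
fruit_turgor <- function(psi_stem, pi_f, aL_fm, transp, V, phi, Y) {
  p_grow <- (aL_fm * (psi_stem + pi_f) - transp + V * phi * Y) /
    (aL_fm + V * phi)
  p_eq <- psi_stem + pi_f - transp / aL_fm          # inflow = 0
  p <- ifelse(p_grow > Y, p_grow, pmin(pmax(p_eq, 0), Y))
  pmax(p, 0)
}

#' Advance fruit water relations over one day
#'
#' Integrates the fruit volume equation dV/dt = A L (psi_stem - psi_f) - T
#' with psi_f = P_f - pi_f, where the turgor P_f follows a quasi-steady
#' plastic-only Lockhart closure: while P_f exceeds the yield threshold the
#' irreversible expansion rate V phi (P_f - Y) absorbs the net inflow; below
#' it the turgor settles where inflow balances transpiration (volume
#' constant), clamped at zero turgor under strong water deficit (net
#' shrinkage). Explicit sub-daily (hourly) steps; osmotic pressure is
#' re-diluted as the volume changes.
#'
#' @param state list per fruit: \code{fm} (g), \code{dm} (g), \code{pools}
#'   (list of sugar g C vectors).
#' @param psi_stem_hours matrix (hours x fruits) or vector of stem water
#'   potential at the bearing unit, MPa.
#' @param vpd_hours matrix/vector of air VPD, hPa, same shape.
#' @param tair_hours air temperature per hour, degC (for van't Hoff).
#' @param params parameter set.
#' @return updated state with elements \code{fm}, \code{water} (g),
#'   \code{turgor} (last hour, MPa), \code{pi_f} (MPa), plus the unchanged
#'   dry-mass fields.
#' @export
fruit_water_step <- function(state, psi_stem_hours, vpd_hours, tair_hours,
                             params = default_params()) {
  fp <- params$fruit
  psi_stem_hours <- as.matrix(psi_stem_hours)
  vpd_hours <- as.matrix(vpd_hours)
  nh <- nrow(psi_stem_hours)
  nf <- ncol(psi_stem_hours)
  dm <- state$dm
  part <- stone_flesh_partition(dm, fp)
  water <- pmax(state$fm - dm, 0.05)                # g = cm3
  turgor <- numeric(nf); pi_f <- numeric(nf)
  for (h in seq_len(nh)) {
    fm <- water + dm
    vol_L <- water / 1000
    pi_f <- osmotic_pressure(state$pools, pmax(vol_L, 1e-5),
                             tair_hours[h] + 273.15, params$sugar,
                             pi_other = fp$pi_other)
    aL_fm <- fp$aL * fm^fp$aL_exp                   # g h-1 MPa-1
    transp <- fruit_transpiration(fm, vpd_hours[h, ], fp)
    turgor <- fruit_turgor(psi_stem_hours[h, ], pi_f, aL_fm, transp,
                           water, fp$phi, fp$yield_threshold)
    psi_f <- turgor - pi_f
    dv <- aL_fm * (psi_stem_hours[h, ] - psi_f) - transp   # g h-1
    water <- water + dv                              # 1 h step
    if (any(water < 0)) {
      bad <- which(water < 0)[1]
      stop(sprintf(paste0("fruit water content went negative (fruit %d, ",
                          "hour %d): fm=%.2f dm=%.2f psi_stem=%.2f"),
                   bad, h, fm[bad], dm[bad], psi_stem_hours[h, bad]))
    }
  }
  state$fm <- water + dm
  state$water <- water
  state$turgor <- turgor
  state$pi_f <- pi_f
  state
}

# time-varying sucrose hydrolysis rate, day-1 (equals 1 at t = K2_2),
# capped for stability
sugar_k2 <- function(t, params = default_params()$sugar) {
  pmin(exp(-params$K2_1 * (t - params$K2_2)), params$k2_cap)
}

#' Advance the fruit sugar pools over one step
#'
#' Four-pool carbon system (sucrose, sorbitol, glucose, fructose): phloem
#' carbon enters as sucrose (share k1) and sorbitol (1 - k1); sucrose is
#' hydrolysed at the declining rate k2(t), split equimolarly (carbon basis)
#' into glucose and fructose; sorbitol converts to fructose (K3) and glucose
#' (K5); glucose and fructose leave the soluble pools for metabolism and
#' structure at k4 = K4_1 x fruit relative growth rate. Integrated with a
#' classical fourth-order Runge-Kutta scheme; pools are clamped at zero.
#'
#' @param pools list of vectors (one element per fruit): \code{sucrose},
#'   \code{sorbitol}, \code{glucose}, \code{fructose}, g C.
#' @param influx carbon influx to the flesh, g C day-1 (per fruit).
#' @param rgr fruit relative growth rate, day-1 (per fruit).
#' @param t days after bloom at the start of the step.
#' @param dt total time to advance, day.
#' @param params sugar block.
#' @return list: updated \code{pools}, plus \code{exported} (cumulative
#'   carbon leaving via k4 during the step, g C, per fruit).
#' @export
sugar_step <- function(pools, influx, rgr, t, dt = 1,
                       params = default_params()$sugar) {
  if (any(influx < 0)) stop("negative carbon influx")
  nstep <- max(1L, ceiling(dt / params$dt))
  h <- dt / nstep
  su <- as.numeric(pools$sucrose); so <- as.numeric(pools$sorbitol)
  g <- as.numeric(pools$glucose); f <- as.numeric(pools$fructose)
  exported <- numeric(length(su))
  k4 <- params$K4_1 * pmax(rgr, 0)
  in_su <- params$k1 * influx
  in_so <- (1 - params$k1) * influx
  k35 <- params$K3 + params$K5
  K3 <- params$K3; K5 <- params$K5
  for (s in seq_len(nstep)) {
    tt <- t + (s - 1) * h
    k2a <- sugar_k2(tt, params)
    k2b <- sugar_k2(tt + h / 2, params)
    k2c <- sugar_k2(tt + h, params)
    # classical RK4, unrolled over the four linear pools
    d1su <- in_su - k2a * su
    d1so <- in_so - k35 * so
    d1g <- 0.5 * k2a * su + K5 * so - k4 * g
    d1f <- 0.5 * k2a * su + K3 * so - k4 * f
    su2 <- su + h / 2 * d1su; so2 <- so + h / 2 * d1so
    g2 <- g + h / 2 * d1g; f2 <- f + h / 2 * d1f
    d2su <- in_su - k2b * su2
    d2so <- in_so - k35 * so2
    d2g <- 0.5 * k2b * su2 + K5 * so2 - k4 * g2
    d2f <- 0.5 * k2b * su2 + K3 * so2 - k4 * f2
    su3 <- su + h / 2 * d2su; so3 <- so + h / 2 * d2so
    g3 <- g + h / 2 * d2g; f3 <- f + h / 2 * d2f
    d3su <- in_su - k2b * su3
    d3so <- in_so - k35 * so3
    d3g <- 0.5 * k2b * su3 + K5 * so3 - k4 * g3
    d3f <- 0.5 * k2b * su3 + K3 * so3 - k4 * f3
    su4 <- su + h * d3su; so4 <- so + h * d3so
    g4 <- g + h * d3g; f4 <- f + h * d3f
    d4su <- in_su - k2c * su4
    d4so <- in_so - k35 * so4
    d4g <- 0.5 * k2c * su4 + K5 * so4 - k4 * g4
    d4f <- 0.5 * k2c * su4 + K3 * so4 - k4 * f4
    su_n <- pmax(su + h / 6 * (d1su + 2 * d2su + 2 * d3su + d4su), 0)
    so_n <- pmax(so + h / 6 * (d1so + 2 * d2so + 2 * d3so + d4so), 0)
    g_n <- pmax(g + h / 6 * (d1g + 2 * d2g + 2 * d3g + d4g), 0)
    f_n <- pmax(f + h / 6 * (d1f + 2 * d2f + 2 * d3f + d4f), 0)
    # the system conserves carbon: d(sum pools) = influx - k4 (C_g + C_f),
    # so the exported integral is recovered from the pool balance exactly
    exported <- exported + influx * h -
      (su_n - su + so_n - so + g_n - g + f_n - f)
    su <- su_n; so <- so_n; g <- g_n; f <- f_n
  }
  list(pools = list(sucrose = su, sorbitol = so, glucose = g, fructose = f),
       exported = exported)
}

#' Fruit composition summaries
#'
#' Converts the sugar carbon pools to sugar masses and expresses them per
#' 100 g fresh mass and per g dry mass, along with the flesh dry matter
#' content.
#'
#' @param state fruit state list: \code{fm}, \code{dm}, \code{pools}.
#' @param params parameter set.
#' @return list with \code{per_fm} and \code{per_dm} (named lists of the
#'   four sugars, g per 100 g FM and g per g DM), \code{total_sugar_fm}
#'   (g per 100 g FM), \code{sugar_mass} (g per fruit) and \code{dmc}.
#' @export
fruit_composition <- function(state, params = default_params()) {
  if (any(state$fm <= 0)) stop("fresh mass must be positive")
  cf <- params$sugar$cf
  part <- stone_flesh_partition(state$dm, params$fruit)
  flesh_fm <- state$fm - part$stone    # stone carries negligible water
  mass <- lapply(names(cf), function(s) state$pools[[s]] / cf[[s]])
  names(mass) <- names(cf)
  per_fm <- lapply(mass, function(m) 100 * m / flesh_fm)
  per_dm <- lapply(mass, function(m) m / pmax(part$flesh, 1e-9))
  tot <- Reduce(`+`, mass)
  list(per_fm = per_fm, per_dm = per_dm,
       total_sugar_fm = 100 * tot / flesh_fm,
       sugar_mass = tot,
       dmc = part$flesh / pmax(flesh_fm, 1e-9))
}
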