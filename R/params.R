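#' Physical constants used throughout the model
#'
#' Fixed CODATA-style values: Stefan-Boltzmann constant, molar latent heat of
#' vaporization of water, molar heat capacity of air, standard atmospheric
#' pressure, gas constant (volume-pressure form used by the van't Hoff
#' relation), molar volume of liquid water and molar mass of water.
#'
#' @return Named list of constants with units in the element names' docs:
#'   \code{sigma} (W m-2 K-4), \code{lambda_mol} (J mol-1),
#'   \code{cp_mol} (J mol-1 K-1), \code{p_atm} (hPa),
#'   \code{R_MPa} (L MPa mol-1 K-1), \code{water_molar_volume} (m3 mol-1),
#'   \code{water_molar_mass} (g mol-1), \code{carbon_molar_mass} (g mol-1).
#' @export
physical_constants <- function() {
  list(
    sigma = 5.670374e-8,
    lambda_mol = 44100,
    cp_mol = 29.14,
    p_atm = 1013,
    R_MPa = 0.008314,
    water_molar_volume = 1.8e-5,
    water_molar_mass = 18.015,
    carbon_molar_mass = 12.011
  )
}

#' Default model parameter set
#'
#' Returns the full parameter list for the simulator. The stomatal, stress
#' response, potential growth, stone/flesh partition and sugar partitioning
#' blocks are the "Elberta" estimates; the remaining blocks (optical
#' properties, boundary-layer and hydraulic coefficients, respiration,
#' reserves, fruit biophysics) are documented defaults in the range a peach
#' physiologist would use, exposed here so they can be overridden.
#'
#' @param ... named overrides, e.g. \code{default_params(latitude = 40)} or
#'   nested via lists, e.g. \code{default_params(stomatal = list(gs_max = 0.1))}
#'   (partial nested lists are merged into the defaults).
#' @return Nested named list of parameters (class \code{orchard_params}).
#' @examples
#' p <- default_params()
#' p$photosynthesis$A_h
#' @export
default_params <- function(...) {
  p <- list(
    latitude = 36.48,          # deg N
    spacing = c(4, 5),         # m x m tree spacing
    base_temp = 7,             # degC, degree-day base (standard for peach)
    harvest_dd = 2625,         # degree-days at harvest

    # diurnal collar water potential construction
    diurnal = list(sunrise = 6, trough = 14, sunset = 20),

    radiation = list(
      par_fraction = 0.48,     # PAR share of global shortwave
      absorptance_par = 0.85,
      absorptance_nir = 0.20,
      transmissivity = 0.75,   # clear-sky atmospheric transmissivity
      leaf_emissivity = 1.0,   # Eq.-style emitted term carries no emissivity
      soil_emissivity = 0.95,
      view_sky = 0.5,          # leaf upper-side view factor to sky
      view_soil = 0.5,         # leaf lower-side view factor to soil
      par_w_to_umol = 4.57     # umol photons per J of PAR
    ),

    stomatal = list(           # Jarvis multiplicative model
      gs_max = 0.0796,         # mol m-2 s-1
      a_par = 0.005,           # (umol m-2 s-1)^-1
      a_vpd = 0.158, b_vpd = 8.06,      # hPa^-1, -
      a_temp = 0.23, b_temp = 22.5,     # degC^-1, -
      a_psi = -8.467, b_psi = 13.129    # MPa^-1, -
    ),

    boundary_layer = list(
      forced_coef = 0.147,     # mol m-2 s-1 per sqrt(m s-1 / m)
      free_coef = 0.055,       # mol m-2 s-1 per (K/m)^(1/4)
      leaf_dim = 0.05,         # m, characteristic leaf dimension
      floor = 0.02             # mol m-2 s-1, minimum conductance
    ),

    hydraulics = list(
      a_k = 5e-3,              # m^1.5 s-1 MPa-1, conductivity scale
      b_k = 2.5,               # diameter exponent
      dpsi_max = 0.447,        # MPa, max stem-to-leaf potential drop
      e_ref_vpd = 30,          # hPa, reference VPD for the E_ref computation
      e_ref_gb = 0.5           # mol m-2 s-1, reference boundary conductance
    ),

    solver = list(
      psi_tol = 2e-4,          # MPa, outer fixed-point residual tolerance
      tleaf_tol = 0.005,       # degC
      resid_tol = 0.01,        # W, energy-balance residual tolerance
      max_iter = 50,
      damping = 0.5            # damping on psi_leaf updates
    ),

    photosynthesis = list(
      P_max0 = 0.02,           # mmol CO2 m-2 s-1 (= 20 umol), unstressed
      A_h = 0.3647,            # MPa-1
      B_h = 6.3667,            # MPa
      alpha = 0.06             # mol CO2 mol photon-1, quantum efficiency
    ),

    respiration = list(        # g C (g DM)-1 day-1 at 20 degC; Q10 = 2
      mrr = c(leafy = 1.9e-3, water_sprout = 1.9e-3, fruit = 1.3e-3,
              old_wood = 5e-5, coarse_root = 1e-4, fine_root = 1.2e-3),
      q10 = 2, t_ref = 20,
      growth_cost = 0.18,      # g C respired per g C incorporated
      carbon_content = 0.45    # g C per g DM
    ),

    growth = list(
      leafy = list(rgr_ini = 0.00036, dm_max = 4.65,
                   dd0 = 0, dd_min = 0, dd_max = 2500),
      water_sprout = list(rgr_ini = 0.0059, dm_max = 11.1,
                          dd0 = 950, dd_min = 2400, dd_max = 2800),
      fruit = list(rgr_ini = 0.0025, dm_max = 35,
                   dd0 = 0, dd_min = 2600, dd_max = 2800),
      sla = 0.0158,            # m2 g-1 specific leaf area
      psi_min = -1.949,        # MPa, growth stops below this
      psi_max = -1.378,        # MPa, no growth limitation above this
      psi_stat = "midday_min"  # or "daytime_mean": which daily psi enters f_psi
      # (the stress thresholds were fitted on midday leaf potentials)
    ),

    allocation = list(
      h = 1.0,                 # distance-decay exponent
      min_distance = 0.05,     # m, self/short distance floor
      target_ratio = 5,        # g shoot per g fine root at equilibrium
      im_clamp = c(0.2, 5),
      reserve_mobilizable = 0.10,  # fraction of pool usable per day
      reserve_cap_frac = 0.20      # cap as fraction of compartment DM
    ),

    fruit = list(
      fs_sat = 3.87,           # g, stone mass saturation
      fs_slope = 0.2164,       # g-1, initial stone partition slope
      flesh_dmc = 0.195,       # target flesh dry matter content
      aL = 0.012,              # g h-1 MPa-1 at FM = 1 g: A*L composite scale
      aL_exp = 2/3,            # allometric exponent of A*L in fresh mass
      phi = 0.01,              # MPa-1 h-1 Lockhart extensibility
      yield_threshold = 0.2,   # MPa Lockhart yield turgor
      transp_coef = 4e-4,      # g h-1 cm-2 hPa-1 skin permeation
      surf_coef = 1.2,         # cm2 at FM = 1 g: surface allometry scale
      surf_exp = 2/3,
      pi_other = 0.25,         # MPa, non-sugar osmolyte contribution
      density = 1.0            # g cm-3 of fruit water
    ),

    sugar = list(
      k1 = 0.3573,             # phloem sucrose carbon share
      K3 = 0.0536,             # day-1, sorbitol -> fructose
      K5 = 0.0598,             # day-1, sorbitol -> glucose
      K2_1 = 0.0879,           # day-1, decay rate of k2(t)
      K2_2 = 74.0405,          # day at which k2(t) = 1 day-1
      K4_1 = 2.3380,           # k4 = K4_1 * fruit RGR
      k2_cap = 5,              # day-1, stability cap on k2(t)
      dt = 0.1,                # day, RK4 step
      cf = c(sucrose = 0.4211, sorbitol = 0.3956,
             glucose = 0.4000, fructose = 0.4000)  # g C per g sugar
    ),

    initial = list(
      leafy_dm = 1.0,          # g per leafy shoot at bloom
      water_sprout_dm = 0.1,   # g per sprout, seeded at emergence dd
      fruit_dm = 0.8,          # g per fruit
      fruit_fm = 5.5,          # g per fruit
      old_wood_dm = 3000,      # g
      coarse_root_dm = 1500,   # g
      fine_root_dm = NULL,     # g; derived as shoots / target ratio at bloom
      reserves = c(old_wood = 120, coarse_root = 60, fine_root = 2),  # g C
      sugar_conc = c(sucrose = 10, sorbitol = 4,
                     glucose = 8, fructose = 8)    # g kg-1 fresh mass
    )
  )
  class(p) <- c("orchard_params", "list")
  modify_params(p, list(...))
}

# recursive merge of override list into defaults
modify_params <- function(p, over) {
  if (length(over) == 0) return(p)
  nm <- names(over)
  if (is.null(nm) || any(nm == "")) stop("parameter overrides must be named")
  for (n in nm) {
    if (is.list(over[[n]]) && is.list(p[[n]])) {
      p[[n]] <- modify_params(p[[n]], over[[n]])
    } else {
      p[[n]] <- over[[n]]
    }
  }
  p
}

#' @export
print.orchard_params <- function(x, ...) {
  cat("<orchard_params> parameter set with blocks:\n")
  cat(" ", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}
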