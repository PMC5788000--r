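#' Coupled hourly solve of leaf energy balance and tree water transfer
#'
#' Nested iterative process closing the loop stomatal conductance -> leaf
#' transpiration -> water flow and potential field -> leaf water potential ->
#' stomatal conductance, for one hour of forcing. The inner problem (sunlit
#' and shaded leaf energy balances at fixed leaf water potential) is solved
#' exactly; the outer fixed point updates leaf water potential with a
#' damping factor until both the potential and the leaf temperatures are
#' stationary.
#'
#' @param tree an \code{orchard_tree}.
#' @param network a \code{hydraulic_network} built from the tree.
#' @param hour_forcing list with \code{global} (W m-2), \code{tair} (degC),
#'   \code{rh} (percent), \code{wind} (m s-1), \code{psi_collar} (MPa),
#'   \code{elevation}, \code{azimuth} (deg).
#' @param sw optional precomputed result of \code{intercept_shortwave} for
#'   this hour (computed here when NULL).
#' @param leaf_area per-unit leaf areas, m2.
#' @param state optional previous-hour state for initialization: list with
#'   \code{psi_leaf}, \code{tleaf_sun}, \code{tleaf_shade}.
#' @param params parameter set.
#' @param gs_scale multiplier on stomatal conductance.
#' @param e_ref_area reference transpiration per leaf area (mol m-2 s-1);
#'   computed from \code{reference_transpiration} when NULL.
#' @param cache optional \code{radiation_cache(tree)} for repeated calls.
#' @param diffuse_coef optional precomputed diffuse-sky interception
#'   coefficient for the current leaf areas.
#' @return list (per-unit vectors unless noted): \code{psi_stem},
#'   \code{psi_leaf} (MPa), \code{tleaf_sun}, \code{tleaf_shade} (degC),
#'   \code{E} (mol s-1), \code{E_sun}, \code{E_shade}, \code{gs_sun},
#'   \code{gs_shade}, \code{gb}, \code{rn} (W), \code{latent},
#'   \code{sensible} (W), \code{iterations}, \code{balance} (node mass
#'   residuals, m3 s-1), \code{sw} (the radiation result used).
#' @export
coupled_hourly_solve <- function(tree, network, hour_forcing, sw = NULL,
                                 leaf_area = tree$fu$leaf_area,
                                 state = NULL, params = default_params(),
                                 gs_scale = 1, e_ref_area = NULL,
                                 cache = NULL, diffuse_coef = NULL) {
  n <- nrow(tree$fu)
  hf <- hour_forcing
  if (is.null(sw))
    sw <- intercept_shortwave(tree, hf$elevation, hf$azimuth, hf$global,
                              leaf_area = leaf_area, params = params,
                              cache = cache, diffuse_coef = diffuse_coef)
  if (is.null(e_ref_area)) e_ref_area <- reference_transpiration(params)
  e_ref <- pmax(e_ref_area * leaf_area, 1e-12)
  dpsi_max <- params$hydraulics$dpsi_max
  sv <- params$solver

  psi_leaf <- if (!is.null(state$psi_leaf)) state$psi_leaf else
    rep(hf$psi_collar, n)
  t_sun <- if (!is.null(state$tleaf_sun)) state$tleaf_sun else
    rep(hf$tair, n)
  t_shade <- if (!is.null(state$tleaf_shade)) state$tleaf_shade else
    rep(hf$tair, n)

  # pool-stacked inputs: first n sunlit, next n shaded. The absorbed
  # shortwave is split between the pools in proportion to the incident PAR
  # flux each pool's leaves actually see (beam + diffuse vs diffuse only).
  rad <- params$radiation
  par_w_sun <- sw$par_sun / rad$par_w_to_umol * sw$area_sun
  par_w_shade <- sw$par_shade / rad$par_w_to_umol * sw$area_shade
  split_sun <- ifelse(par_w_sun + par_w_shade > 0,
                      par_w_sun / (par_w_sun + par_w_shade),
                      sw$area_sun / pmax(leaf_area, 1e-12))
  tot_sw <- sw$par_abs + sw$nir_abs
  sw_abs <- c(tot_sw * split_sun, tot_sw * (1 - split_sun))
  area2 <- c(sw$area_sun, sw$area_shade)
  par2 <- c(sw$par_sun, sw$par_shade)

  iterations <- 0L
  psi_prev <- NULL
  g_prev <- NULL
  repeat {
    iterations <- iterations + 1L
    eb <- solve_leaf_energy_balance(
      sw_abs, area2, par2, hf$tair, hf$rh, hf$wind,
      psi_leaf = c(psi_leaf, psi_leaf), params = params,
      gs_scale = gs_scale, t_init = c(t_sun, t_shade))
    E_fu <- eb$E[1:n] + eb$E[(n + 1):(2 * n)]
    hyd <- solve_hydraulic_network(network, hf$psi_collar, E_fu)
    psi_new <- leaf_potential(hyd$psi_stem, E_fu, e_ref, dpsi_max)
    g <- psi_new - psi_leaf                 # fixed-point residual
    d_psi <- max(abs(g))
    d_t <- max(abs(c(eb$t_leaf[1:n] - t_sun,
                     eb$t_leaf[(n + 1):(2 * n)] - t_shade)))
    t_sun <- eb$t_leaf[1:n]
    t_shade <- eb$t_leaf[(n + 1):(2 * n)]
    if (d_psi < sv$psi_tol && d_t < sv$tleaf_tol) break
    if (iterations >= sv$max_iter)
      stop(sprintf(paste0("coupled hourly solve did not converge in %d ",
                          "iterations (last |d_psi| = %.2e MPa, ",
                          "|d_T| = %.2e degC)"), sv$max_iter, d_psi, d_t))
    if (is.null(g_prev)) {
      step <- sv$damping * g                # damped start-up step
    } else {
      # componentwise secant (Steffensen) acceleration of the fixed point,
      # safeguarded by the damped step where the denominator degenerates
      dg <- g - g_prev
      dx <- psi_leaf - psi_prev
      sec <- -g * dx / dg
      bad <- !is.finite(sec) | abs(dg) < 1e-12 | abs(sec) > 0.5
      sec[bad] <- sv$damping * g[bad]
      step <- sec
    }
    psi_prev <- psi_leaf
    g_prev <- g
    psi_leaf <- psi_leaf + step
  }
  list(psi_stem = hyd$psi_stem, psi_leaf = psi_leaf,
       tleaf_sun = t_sun, tleaf_shade = t_shade,
       E = E_fu, E_sun = eb$E[1:n], E_shade = eb$E[(n + 1):(2 * n)],
       gs_sun = eb$gs[1:n], gs_shade = eb$gs[(n + 1):(2 * n)],
       gb = eb$gb[1:n],
       rn = eb$rn[1:n] + eb$rn[(n + 1):(2 * n)],
       latent = eb$latent[1:n] + eb$latent[(n + 1):(2 * n)],
       sensible = eb$sensible[1:n] + eb$sensible[(n + 1):(2 * n)],
       iterations = iterations, balance = hyd$balance, sw = sw)
}
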