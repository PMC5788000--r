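#' Degree-day window factor for potential growth
#'
#' Piecewise factor: 0 before organ emergence (dd0), 1 up to dd_min, a
#' linear decline from 1 at dd_min to 0 at dd_max, and 0 beyond.
#'
#' @param dd cumulative degree-days (>= 0, vectorized).
#' @param params organ growth block with \code{dd0}, \code{dd_min},
#'   \code{dd_max}.
#' @return factor in [0, 1].
#' @export
f_dd <- function(dd, params) {
  stopifnot(params$dd0 <= params$dd_min, params$dd_min < params$dd_max)
  ifelse(dd < params$dd0, 0,
  ifelse(dd < params$dd_min, 1,
  ifelse(dd < params$dd_max,
         (params$dd_max - dd) / (params$dd_max - params$dd_min), 0)))
}

#' Leaf-water-potential reduction factor for vegetative growth
#'
#' 0 below psi_min, linear between psi_min and psi_max, 1 above psi_max:
#' the direct (sink-side) effect of water deficit on potential growth.
#'
#' @param psi_leaf leaf water potential, MPa (vectorized).
#' @param psi_min potential below which growth is null, MPa.
#' @param psi_max potential above which growth is unlimited, MPa.
#' @return factor in [0, 1].
#' @examples
#' f_psi(c(-2.5, -1.6635, -1.0))
#' @export
f_psi <- function(psi_leaf, psi_min = default_params()$growth$psi_min,
                  psi_max = default_params()$growth$psi_max) {
  stopifnot(psi_min < psi_max)
  pmin(1, pmax(0, (psi_leaf - psi_min) / (psi_max - psi_min)))
}

#' Potential growth increment of a vegetative organ
#'
#' Logistic-type potential growth in thermal time, modulated by the root-
#' shoot imbalance Im, the degree-day window and the water-stress factor:
#' dDM = RGR_ini Im^-1 f(dd) DM (1 - DM Im^-1 / DM_max) f(psi) ddd,
#' floored at zero.
#'
#' @param dm current dry mass, g (>= 0).
#' @param ddd degree-day increment (>= 0).
#' @param im root-shoot imbalance (1 at the target ratio).
#' @param fdd degree-day window factor in [0, 1].
#' @param fpsi water-stress factor in [0, 1].
#' @param params organ growth block (\code{rgr_ini}, \code{dm_max}).
#' @return potential dry-mass increment, g (vectorized).
#' @export
potential_growth_step <- function(dm, ddd, im, fdd, fpsi, params) {
  if (params$dm_max <= 0) stop("dm_max must be positive")
  if (any(dm < 0) || any(ddd < 0)) stop("negative mass or thermal time")
  pmax(0, params$rgr_ini / im * fdd * dm *
         (1 - dm / (im * params$dm_max)) * fpsi * ddd)
}

#' Potential growth (carbon demand) of one fruit
#'
#' The same logistic potential-growth form with the imbalance and the
#' water-stress factor fixed at 1: fruit sink strength responds to water
#' status only through carbon supply and the biophysics of water inflow,
#' not through a direct turgor limitation of its dry growth.
#'
#' @param dm current fruit dry mass, g.
#' @param ddd degree-day increment.
#' @param dd current cumulative degree-days (for the fruit dd window).
#' @param params fruit growth block.
#' @return potential dry-mass increment per fruit, g (vectorized).
#' @export
fruit_demand_step <- function(dm, ddd, dd, params = default_params()$growth$fruit) {
  potential_growth_step(dm, ddd, im = 1, fdd = f_dd(dd, params), fpsi = 1,
                        params = params)
}

#' Distance-decay allocation of carbon from sources to sinks
#'
#' Each source distributes its supply over the sinks in proportion to
#' demand x distance^-h; no sink receives more than its demand and no
#' source exports more than its supply. Excess supply freed by saturated
#' sinks is re-offered to the unsatisfied ones (iterative water-filling).
#'
#' @param supply numeric vector of source supplies, g C (>= 0).
#' @param demand numeric vector of sink demands, g C (>= 0).
#' @param dist matrix (sources x sinks) of distances, m; floored at a small
#'   positive value.
#' @param h distance-decay exponent (>= 0).
#' @param min_distance floor applied to \code{dist}.
#' @return list with \code{alloc} (sources x sinks matrix, g C),
#'   \code{received} (per sink), \code{leftover} (per source).
#' @export
allocate_carbon <- function(supply, demand, dist, h = 1,
                            min_distance = 0.05) {
  if (h < 0) stop("distance exponent must be >= 0")
  if (any(supply < -1e-9) || any(demand < -1e-9))
    stop("negative supply or demand")
  supply <- pmax(supply, 0)
  demand <- pmax(demand, 0)
  ns <- length(supply); nk <- length(demand)
  dist <- pmax(as.matrix(dist), min_distance)
  stopifnot(nrow(dist) == ns, ncol(dist) == nk)
  w0 <- dist^(-h)
  alloc <- matrix(0, ns, nk)
  left <- supply
  need <- demand
  for (pass in 1:50) {
    if (sum(left) <= 1e-15 || sum(need) <= 1e-15) break
    w <- w0 * matrix(need, ns, nk, byrow = TRUE)
    rs <- rowSums(w)
    active <- rs > 0 & left > 0
    if (!any(active)) break
    offer <- (w[active, , drop = FALSE] / rs[active]) * left[active]
    offered <- colSums(offer)
    take_frac <- ifelse(offered > 0, pmin(1, need / offered), 0)
    taken <- sweep(offer, 2, take_frac, "*")
    alloc[active, ] <- alloc[active, ] + taken
    left[active] <- left[active] - rowSums(taken)
    need <- pmax(0, demand - colSums(alloc))
    if (all(take_frac >= 1 - 1e-12)) break   # nothing was saturated
  }
  list(alloc = alloc, received = colSums(alloc), leftover = left)
}

#' Root-shoot imbalance
#'
#' Ratio of the shoot:fine-root mass ratio to its target value, clamped;
#' equals 1 at the equilibrium ratio.
#'
#' @param shoot_dm total leafy shoot (+ water sprout) dry mass, g.
#' @param fine_root_dm fine root dry mass, g.
#' @param params allocation block (\code{target_ratio}, \code{im_clamp}).
#' @return dimensionless imbalance Im > 0.
#' @export
tree_imbalance <- function(shoot_dm, fine_root_dm,
                           params = default_params()$allocation) {
  r <- (shoot_dm / max(fine_root_dm, 1e-9)) / params$target_ratio
  min(max(r, params$im_clamp[1]), params$im_clamp[2])
}

#' One day of the whole-tree carbon budget
#'
#' Priority sequence: maintenance respiration first (drawing mobilizable
#' reserves when assimilate is insufficient), then vegetative growth (leafy
#' shoots, water sprouts, fine roots), then fruit growth, each paying its
#' growth respiration cost and allocated by \code{allocate_carbon}; any
#' surplus is stored passively in reserves up to the compartment caps, and
#' what exceeds the caps accrues to perennial structures (old wood and
#' coarse roots). The carbon ledger closes exactly:
#' assimilation + reserve draw - reserve storage =
#' maintenance + growth x (1 + cost) + perennial growth x (1 + cost).
#'
#' @param state tree carbon state list (see \code{initial_tree_state}).
#' @param assim per-FU gross assimilation for the day, g C.
#' @param maint named maintenance requirements per compartment, g C.
#' @param demand_veg per-FU leafy demand plus named water-sprout and
#'   fine-root demands, g C (vector: one per FU then \code{ws}, \code{root}).
#' @param demand_fruit per-FU fruit demand, g C.
#' @param dist_veg,dist_fruit distance matrices (sources x sinks) for the
#'   two allocation passes; the sources are the FUs (reserves buffer
#'   maintenance only and never fund growth).
#' @param params parameter set.
#' @return list with per-sink growth carbon (g C), reserve changes, the
#'   starvation deficit (g C of unpaid maintenance, 0 normally) and a
#'   \code{ledger} list whose \code{residual} is the closure error (g C).
#' @export
daily_carbon_budget <- function(state, assim, maint, demand_veg,
                                demand_fruit, dist_veg, dist_fruit,
                                params = default_params()) {
  al <- params$allocation
  cost <- params$respiration$growth_cost
  n_fu <- length(assim)
  reserves <- state$reserves
  mobilizable <- al$reserve_mobilizable * reserves

  # --- maintenance, FU-local first, then pooled with reserves ---
  total_maint <- sum(maint)
  pool <- sum(assim)
  draw <- 0
  starvation <- 0
  if (pool >= total_maint) {
    pool <- pool - total_maint
  } else {
    need <- total_maint - pool
    draw <- min(need, sum(mobilizable))
    starvation <- need - draw
    pool <- 0
  }
  # proportional draw across reserve compartments
  if (draw > 0) {
    frac <- draw / sum(mobilizable)
    reserves <- reserves - frac * mobilizable
  }
  if (starvation > 0) {
    # no growth on a starvation day
    return(list(growth_veg = numeric(length(demand_veg)) * 0,
                growth_fruit = numeric(n_fu) * 0,
                perennial_growth = 0,
                reserves = reserves, reserve_draw = draw, reserve_store = 0,
                starvation = starvation,
                ledger = list(assim = sum(assim), draw = draw, store = 0,
                              maint = total_maint - starvation, growth = 0,
                              residual = 0)))
  }

  # supplies for growth: surplus assimilate, staying with its FU (the
  # maintenance charge is shared proportionally); reserves buffer
  # maintenance only and never fund growth
  fu_supply <- if (sum(assim) > 0) pmax(0, assim * pool / sum(assim)) else
    rep(0, n_fu)

  # --- pass 1: vegetative sinks (cost-inflated demands) ---
  a1 <- allocate_carbon(fu_supply, demand_veg * (1 + cost), dist_veg,
                        h = al$h, min_distance = al$min_distance)
  growth_veg <- a1$received / (1 + cost)
  # --- pass 2: fruit sinks get what is left ---
  a2 <- allocate_carbon(a1$leftover, demand_fruit * (1 + cost), dist_fruit,
                        h = al$h, min_distance = al$min_distance)
  growth_fruit <- a2$received / (1 + cost)
  leftover <- a2$leftover

  # --- surplus: passive storage up to caps, overflow to perennial growth ---
  surplus <- sum(leftover)
  caps <- al$reserve_cap_frac * params$respiration$carbon_content *
    c(old_wood = state$old_wood_dm, coarse_root = state$coarse_root_dm,
      fine_root = state$fine_root_dm)
  room <- pmax(0, caps - reserves)
  store <- min(surplus, sum(room))
  if (store > 0) reserves <- reserves + store * room / sum(room)
  perennial_c <- (surplus - store) / (1 + cost)

  ledger_growth <- (sum(growth_veg) + sum(growth_fruit) + perennial_c) *
    (1 + cost)
  residual <- sum(assim) + draw - store -
    (total_maint + ledger_growth)
  list(growth_veg = growth_veg, growth_fruit = growth_fruit,
       perennial_growth = perennial_c,
       reserves = reserves, reserve_draw = draw, reserve_store = store,
       starvation = 0,
       ledger = list(assim = sum(assim), draw = draw, store = store,
                     maint = total_maint, growth = ledger_growth,
                     residual = residual))
}
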