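#' Initial carbon and fruit state of a tree
#'
#' Sets the bloom-time compartment dry masses, reserve pools, and per-fruit
#' water and sugar state from the \code{initial} parameter block.
#'
#' @param tree an \code{orchard_tree}.
#' @param params parameter set.
#' @return list with per-unit and tree-level state vectors.
#' @export
initial_tree_state <- function(tree, params = default_params()) {
  ini <- params$initial
  fu <- tree$fu
  n <- nrow(fu)
  is_ws <- fu$is_ws
  # leafy_dm is the representative per-shoot dry mass of each unit; the
  # unit total is leafy_dm * n_shoots (ws pool starts at its dd0)
  leafy <- ifelse(is_ws, 0, ini$leafy_dm)
  fruit_dm <- rep(ini$fruit_dm, n)
  fruit_fm <- rep(ini$fruit_fm, n)
  conc <- ini$sugar_conc                          # g sugar per kg FM
  cf <- params$sugar$cf
  part <- stone_flesh_partition(fruit_dm, params$fruit)
  flesh_fm <- fruit_fm - part$stone
  pools <- lapply(names(cf), function(s)
    conc[[s]] / 1000 * flesh_fm * cf[[s]])
  names(pools) <- names(cf)
  list(
    leafy_dm = leafy,
    ws_dm = 0,                       # per sprout; emerges at its dd0
    ws_seeded = FALSE,
    leaf_area = ifelse(is_ws, 0, params$growth$sla * leafy * fu$n_shoots),
    fruit_dm = fruit_dm, fruit_fm = fruit_fm,
    fruit_water = fruit_fm - fruit_dm,
    pools = pools,
    old_wood_dm = ini$old_wood_dm,
    coarse_root_dm = ini$coarse_root_dm,
    fine_root_dm = if (is.null(ini$fine_root_dm))
      sum(leafy * fu$n_shoots) / params$allocation$target_ratio else
        ini$fine_root_dm,
    reserves = ini$reserves,
    im = 1,
    sugar_influx_cum = numeric(n),
    sugar_export_cum = numeric(n)
  )
}

# hypothesis wiring: which water-stress limitations are active
hypothesis_switches <- function(hypothesis = c("both", "none",
                                               "photosynthesis_only",
                                               "growth_only")) {
  hypothesis <- match.arg(hypothesis)
  list(photo = hypothesis %in% c("both", "photosynthesis_only"),
       growth = hypothesis %in% c("both", "growth_only"))
}

#' Simulate one growing season
#'
#' Daily loop (bloom to harvest at the configured degree-day total) with
#' hourly physics: radiation interception, coupled energy balance and water
#' transfer, and photosynthesis are computed hour by hour; carbon allocation,
#' organ growth, fruit water relations and sugar metabolism advance daily.
#'
#' @param tree an \code{orchard_tree}.
#' @param forcing an \code{orchard_forcing} (or compatible list) covering
#'   bloom to harvest.
#' @param params parameter set.
#' @param hypothesis which direct water-stress limitations are wired in:
#'   \code{"both"} (default), \code{"none"}, \code{"photosynthesis_only"}
#'   (light-saturated photosynthesis responds to leaf water potential while
#'   the growth reduction function is forced to 1), or \code{"growth_only"}
#'   (the converse). Water transfer, stomata and fruit water inflow always
#'   respond to water status.
#' @param hourly_out optional CSV path for per-FU hourly diagnostics.
#' @param daily_out optional CSV path for the daily state table.
#' @return object of class \code{season_result}: list with \code{daily}
#'   (data frame of tree-level trajectories), \code{fu_harvest} (per-unit
#'   harvest table), \code{totals} (harvest summary scalars), \code{state}
#'   (final state), \code{checks} (max carbon-ledger and hydraulic
#'   residuals), and the run settings.
#' @export
simulate_season <- function(tree, forcing, params = default_params(),
                            hypothesis = "both",
                            hourly_out = NULL, daily_out = NULL) {
  sw_on <- hypothesis_switches(hypothesis)
  fu <- tree$fu
  n <- nrow(fu)
  is_ws <- fu$is_ws
  ws_idx <- which(is_ws)
  n_shoots <- fu$n_shoots
  n_sprouts <- if (length(ws_idx)) fu$n_shoots[ws_idx] else 0
  net <- hydraulic_network(tree, params)
  cache <- radiation_cache(tree)
  e_ref_area <- reference_transpiration(params)
  state <- initial_tree_state(tree, params)
  cc <- params$respiration$carbon_content
  cost <- params$respiration$growth_cost
  gp <- params$growth
  mrr <- params$respiration$mrr

  weather <- forcing$weather
  boundary <- forcing$boundary
  dd_tab <- forcing$dd
  dates <- dd_tab$date
  dd_series <- dd_tab$dd
  if (max(dd_series) < params$harvest_dd - 1e-6)
    warning("forcing ends before the harvest degree-day total")

  # distances for allocation: units to unit sinks and to the collar
  pos <- as.matrix(fu[, c("x", "y", "z")])
  dist_units <- as.matrix(stats::dist(pos))
  dist_collar <- sqrt(rowSums(pos^2))

  daily <- vector("list", length(dates))
  fu_leafy <- matrix(NA_real_, n, length(dates))
  fu_fruit <- matrix(NA_real_, n, length(dates))
  ws_daily <- rep(NA_real_, length(dates))
  hourly_rows <- if (!is.null(hourly_out)) vector("list", length(dates)) else NULL
  max_ledger <- 0; max_balance <- 0
  assim_cum <- 0
  veg_growth_cum <- 0; perennial_growth_cum <- 0
  prev_state_h <- NULL
  dd_prev <- 0
  harvested <- FALSE

  for (di in seq_along(dates)) {
    date <- dates[di]
    wd <- weather[weather$date == date, ]
    wd <- wd[order(wd$hour), ]
    bd <- boundary[boundary$date == date, ]
    psi_collar_h <- collar_potential_series(
      bd$psi_predawn_MPa, bd$psi_midday_MPa,
      sunrise = params$diurnal$sunrise, trough = params$diurnal$trough,
      sunset = params$diurnal$sunset, hours = wd$hour)
    doy <- as.integer(format(date, "%j"))
    sun <- solar_position(params$latitude, doy, wd$hour)

    dcoef <- diffuse_interception_coef(cache, state$leaf_area)
    assim_day <- numeric(n)
    e_sum <- numeric(n); psi_e_sum <- numeric(n)
    psi_day_sum <- numeric(n); n_daylight <- 0
    psi_min_day <- numeric(n)
    psi_stem_hours <- matrix(rep(psi_collar_h, each = n), ncol = n,
                             byrow = TRUE)   # hours x units
    vpd_hours <- pmax(saturation_vp(wd$tair_C) * (1 - wd$rh_pct / 100), 0)
    vpd_mat <- matrix(vpd_hours, nrow = length(wd$hour), ncol = n)

    for (hi in seq_along(wd$hour)) {
      if (wd$rad_Wm2[hi] <= 0 || sun$elevation[hi] <= 0) next  # night
      hf <- list(global = wd$rad_Wm2[hi], tair = wd$tair_C[hi],
                 rh = wd$rh_pct[hi], wind = wd$wind_ms[hi],
                 psi_collar = psi_collar_h[hi],
                 elevation = sun$elevation[hi], azimuth = sun$azimuth[hi])
      cs <- coupled_hourly_solve(tree, net, hf, leaf_area = state$leaf_area,
                                 state = prev_state_h, params = params,
                                 cache = cache, e_ref_area = e_ref_area,
                                 diffuse_coef = dcoef)
      prev_state_h <- cs
      psi_stem_hours[hi, ] <- cs$psi_stem
      max_balance <- max(max_balance, max(abs(cs$balance)))

      p_max <- if (sw_on$photo) pmax_water_limited(pmin(cs$psi_leaf, -1e-6),
                                                   params$photosynthesis)
               else rep(params$photosynthesis$P_max0, n)
      assim_h <- fu_assimilation(cs$sw$area_sun, cs$sw$area_shade,
                                 cs$sw$par_sun, cs$sw$par_shade,
                                 p_max, params$photosynthesis$alpha)
      assim_day <- assim_day + assim_h
      e_sum <- e_sum + cs$E
      psi_e_sum <- psi_e_sum + cs$E * cs$psi_leaf
      psi_day_sum <- psi_day_sum + cs$psi_leaf
      n_daylight <- n_daylight + 1
      psi_min_day <- pmin(psi_min_day, cs$psi_leaf)
      if (!is.null(hourly_rows)) {
        hourly_rows[[di]] <- rbind(hourly_rows[[di]], data.frame(
          date = date, hour = wd$hour[hi], fu_id = fu$id,
          psi_stem = cs$psi_stem, psi_leaf = cs$psi_leaf,
          tleaf_sun = cs$tleaf_sun, tleaf_shade = cs$tleaf_shade,
          E_mol_s = cs$E, gs = cs$gs_sun, gb = cs$gb, Rn_W = cs$rn))
      }
    }

    # stress statistic entering the growth reduction (per unit)
    psi_stat <- if (n_daylight == 0) {
      rep(psi_collar_h[1], n)
    } else if (gp$psi_stat == "midday_min") {
      psi_min_day
    } else {
      ifelse(e_sum > 1e-12, psi_e_sum / pmax(e_sum, 1e-12),
             psi_day_sum / n_daylight)
    }

    dd <- dd_series[di]
    ddd <- dd - dd_prev
    dd_prev <- dd

    # water sprout pool emerges at its dd0
    if (!state$ws_seeded && dd >= gp$water_sprout$dd0) {
      state$ws_dm <- params$initial$water_sprout_dm
      state$ws_seeded <- TRUE
    }

    # maintenance (g C, whole day, hourly Q10 response)
    maint <- c(
      leafy = maintenance_respiration(sum(state$leafy_dm * n_shoots),
                                      wd$tair_C, mrr[["leafy"]]),
      ws = maintenance_respiration(state$ws_dm * n_sprouts, wd$tair_C,
                                   mrr[["water_sprout"]]),
      fruit = maintenance_respiration(sum(state$fruit_dm * fu$n_fruits),
                                      wd$tair_C, mrr[["fruit"]]),
      old_wood = maintenance_respiration(state$old_wood_dm, wd$tair_C,
                                         mrr[["old_wood"]]),
      coarse_root = maintenance_respiration(state$coarse_root_dm, wd$tair_C,
                                            mrr[["coarse_root"]]),
      fine_root = maintenance_respiration(state$fine_root_dm, wd$tair_C,
                                          mrr[["fine_root"]])
    )

    # potential growth demands (g DM), converted to g C for allocation
    fpsi_u <- if (sw_on$growth) f_psi(psi_stat, gp$psi_min, gp$psi_max)
              else rep(1, n)
    im <- state$im
    dem_leafy_dm <- ifelse(is_ws, 0, n_shoots *
      potential_growth_step(state$leafy_dm, ddd, im,
                            f_dd(dd, gp$leafy), fpsi_u, gp$leafy))
    dem_ws_dm <- n_sprouts *
      potential_growth_step(state$ws_dm, ddd, im,
                            f_dd(dd, gp$water_sprout),
                            if (length(ws_idx)) fpsi_u[ws_idx] else
                              min(fpsi_u),
                            gp$water_sprout)
    shoot_dm_now <- sum(state$leafy_dm * n_shoots) + state$ws_dm * n_sprouts
    shoot_pot <- shoot_dm_now + sum(dem_leafy_dm) + dem_ws_dm
    dem_root_dm <- max(0, shoot_pot / params$allocation$target_ratio -
                         state$fine_root_dm)
    dem_fruit_dm <- fu$n_fruits *
      fruit_demand_step(state$fruit_dm, ddd, dd, gp$fruit)

    # allocation: vegetative sinks = per-unit leafy, ws pool, fine roots
    sink_veg_dem <- c(dem_leafy_dm, ws = dem_ws_dm, root = dem_root_dm) * cc
    dist_veg <- cbind(dist_units,
                      ws = if (length(ws_idx)) dist_units[, ws_idx] else
                        dist_collar,
                      root = dist_collar)
    dist_fruit <- dist_units
    bud <- daily_carbon_budget(state, assim_day, maint,
                               sink_veg_dem, dem_fruit_dm * cc,
                               dist_veg, dist_fruit, params)
    max_ledger <- max(max_ledger,
                      abs(bud$ledger$residual) /
                        max(bud$ledger$assim + bud$ledger$draw, 1e-9))

    # update dry masses
    g_leafy_dm <- bud$growth_veg[seq_len(n)] / cc        # g DM, unit total
    g_ws_dm <- bud$growth_veg[n + 1] / cc                # g DM, pool total
    g_root_dm <- bud$growth_veg[n + 2] / cc
    g_fruit_dm <- ifelse(fu$n_fruits > 0,
                         bud$growth_fruit / cc / pmax(fu$n_fruits, 1), 0)
    state$leafy_dm <- state$leafy_dm +
      ifelse(is_ws, 0, g_leafy_dm / pmax(n_shoots, 1))
    state$ws_dm <- state$ws_dm + if (n_sprouts > 0) g_ws_dm / n_sprouts else 0
    state$fine_root_dm <- state$fine_root_dm + g_root_dm
    fruit_dm_prev <- state$fruit_dm
    state$fruit_dm <- state$fruit_dm + g_fruit_dm
    per_dm <- bud$perennial_growth / cc
    state$old_wood_dm <- state$old_wood_dm + per_dm * 2 / 3
    state$coarse_root_dm <- state$coarse_root_dm + per_dm / 3
    state$reserves <- bud$reserves
    veg_growth_cum <- veg_growth_cum + sum(g_leafy_dm) + g_ws_dm + g_root_dm
    perennial_growth_cum <- perennial_growth_cum + per_dm +
      (bud$reserve_store - bud$reserve_draw) / cc
    assim_cum <- assim_cum + sum(assim_day)

    # leaf areas follow shoot dry mass
    state$leaf_area <- ifelse(is_ws, gp$sla * state$ws_dm * n_sprouts,
                              gp$sla * state$leafy_dm * n_shoots)
    state$im <- tree_imbalance(sum(state$leafy_dm * n_shoots) +
                                 state$ws_dm * n_sprouts,
                               state$fine_root_dm, params$allocation)

    # fruit water relations (per-unit representative fruit)
    fr_state <- list(fm = state$fruit_fm, dm = state$fruit_dm,
                     pools = state$pools)
    fr_state <- fruit_water_step(fr_state, psi_stem_hours, vpd_mat,
                                 wd$tair_C, params)
    state$fruit_fm <- fr_state$fm
    state$fruit_water <- fr_state$water

    # sugar metabolism: flesh share of the day's fruit growth carbon
    dflesh_ddm <- 1 - params$fruit$fs_slope * params$fruit$fs_sat *
      exp(-params$fruit$fs_slope * fruit_dm_prev)
    influx <- pmax(g_fruit_dm, 0) * cc * pmax(pmin(dflesh_ddm, 1), 0)
    rgr_fruit <- ifelse(fruit_dm_prev > 0, g_fruit_dm / fruit_dm_prev, 0)
    sg <- sugar_step(state$pools, influx, rgr_fruit, t = di - 1, dt = 1,
                     params = params$sugar)
    state$pools <- sg$pools
    state$sugar_influx_cum <- state$sugar_influx_cum + influx
    state$sugar_export_cum <- state$sugar_export_cum + sg$exported

    daily[[di]] <- data.frame(
      date = date, dd = dd,
      assim_gC = sum(assim_day),
      leafy_dm = sum(state$leafy_dm * n_shoots),
      ws_dm = state$ws_dm * n_sprouts,
      fruit_dm_mean = sum(state$fruit_dm * fu$n_fruits) /
        max(sum(fu$n_fruits), 1),
      fruit_fm_mean = sum(state$fruit_fm * fu$n_fruits) /
        max(sum(fu$n_fruits), 1),
      fine_root_dm = state$fine_root_dm,
      old_wood_dm = state$old_wood_dm,
      coarse_root_dm = state$coarse_root_dm,
      reserves_gC = sum(state$reserves),
      im = state$im,
      ledger_residual = bud$ledger$residual,
      starvation_gC = bud$starvation,
      psi_stat_mean = mean(psi_stat)
    )
    fu_leafy[, di] <- state$leafy_dm * n_shoots
    fu_fruit[, di] <- state$fruit_dm
    ws_daily[di] <- state$ws_dm * n_sprouts
    if (dd >= params$harvest_dd - 1e-6) { harvested <- TRUE; break }
  }

  daily <- do.call(rbind, daily[!vapply(daily, is.null, logical(1))])
  comp <- fruit_composition(list(fm = state$fruit_fm, dm = state$fruit_dm,
                                 pools = state$pools), params)
  nf <- fu$n_fruits
  wnf <- function(x) sum(x * nf) / max(sum(nf), 1)
  fu_harvest <- data.frame(
    fu_id = fu$id, is_ws = is_ws, n_fruits = nf,
    leafy_dm = state$leafy_dm * n_shoots, leaf_area = state$leaf_area,
    fruit_dm = state$fruit_dm, fruit_fm = state$fruit_fm,
    dmc = comp$dmc,
    sucrose_fm = comp$per_fm$sucrose, sorbitol_fm = comp$per_fm$sorbitol,
    glucose_fm = comp$per_fm$glucose, fructose_fm = comp$per_fm$fructose,
    sugar_mass = comp$sugar_mass
  )
  totals <- c(
    assim_gC = assim_cum,
    veg_growth_dm = veg_growth_cum,
    perennial_growth_dm = perennial_growth_cum,
    fruit_dm = wnf(state$fruit_dm),
    fruit_fm = wnf(state$fruit_fm),
    dmc = wnf(comp$dmc),
    sugar_conc_fm = sum(comp$total_sugar_fm * nf) / max(sum(nf), 1),
    sugar_mass = wnf(comp$sugar_mass),
    ws_dm = state$ws_dm * n_sprouts,
    leafy_dm = sum(state$leafy_dm * n_shoots)
  )
  kept <- seq_len(nrow(daily))
  res <- list(daily = daily, fu_harvest = fu_harvest, totals = totals,
              fu_daily = list(dates = dates[kept],
                              leafy = fu_leafy[, kept, drop = FALSE],
                              fruit = fu_fruit[, kept, drop = FALSE],
                              ws = ws_daily[kept]),
              state = state,
              checks = c(max_ledger_rel = max_ledger,
                         max_hydraulic_balance = max_balance),
              harvested = harvested, hypothesis = hypothesis,
              profile = forcing$profile)
  class(res) <- c("season_result", "list")
  if (!is.null(daily_out)) utils::write.csv(daily, daily_out,
                                            row.names = FALSE)
  if (!is.null(hourly_out))
    utils::write.csv(do.call(rbind, hourly_rows), hourly_out,
                     row.names = FALSE)
  res
}

#' @export
print.season_result <- function(x, ...) {
  cat(sprintf("<season_result> %s / %s, %d days%s\n",
              x$profile %||% "?", x$hypothesis, nrow(x$daily),
              if (x$harvested) " (harvest reached)" else ""))
  cat(sprintf("  cumulative assimilation %.1f g C; mean fruit FM %.1f g; dmc %.3f\n",
              x$totals["assim_gC"], x$totals["fruit_fm"], x$totals["dmc"]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
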