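#' Relative root mean square error
#'
#' RMSE divided by the mean of the observations: the dimensionless
#' goodness-of-fit score used throughout the model evaluation.
#'
#' @param observed,simulated numeric vectors of equal length (>= 1).
#' @return dimensionless RRMSE.
#' @examples
#' rrmse(c(2, 4), c(3, 3))  # 1/3
#' @export
rrmse <- function(observed, simulated) {
  stopifnot(length(observed) == length(simulated), length(observed) >= 1)
  m <- mean(observed)
  if (m == 0) stop("mean of observations is zero")
  sqrt(mean((observed - simulated)^2)) / m
}

#' Global calibration criterion
#'
#' Weighted sum, over the three observed variables (leafy shoot, water
#' sprout and fruit dry mass), of the squared observation-simulation
#' differences averaged within each fruiting unit and then across units,
#' each variable weighted by the inverse of its empirical variance over all
#' observation cells.
#'
#' @param obs,sim long-format data frames with columns \code{fu_id},
#'   \code{date}, \code{variable} (one of \code{"leafy"}, \code{"ws"},
#'   \code{"fruit"}) and \code{value}; \code{sim} must cover every obs cell.
#' @return the criterion value (dimensionless, 0 for a perfect fit).
#' @export
criterion_a <- function(obs, sim) {
  need <- c("fu_id", "date", "variable", "value")
  stopifnot(all(need %in% names(obs)), all(need %in% names(sim)))
  m <- merge(obs, sim, by = c("fu_id", "date", "variable"),
             suffixes = c("_obs", "_sim"))
  if (nrow(m) < nrow(obs)) stop("simulated values missing for some cells")
  total <- 0
  for (v in unique(obs$variable)) {
    mv <- m[m$variable == v, ]
    s2 <- stats::var(mv$value_obs)
    if (!is.finite(s2) || s2 <= 0) stop("zero variance for variable ", v)
    sq <- (mv$value_obs - mv$value_sim)^2
    per_fu <- tapply(sq, mv$fu_id, mean)
    total <- total + mean(per_fu) / s2
  }
  total
}

# cumulative thermal-time transform: integral of the dd window factor
f_dd_integral <- function(dd, p) {
  span <- p$dd_max - p$dd_min
  ifelse(dd <= p$dd0, 0,
  ifelse(dd <= p$dd_min, dd - p$dd0,
  ifelse(dd <= p$dd_max,
         (p$dd_min - p$dd0) + (span^2 - (p$dd_max - dd)^2) / (2 * span),
         (p$dd_min - p$dd0) + span / 2)))
}

# closed-form logistic potential-growth trajectory in transformed time
potential_growth_curve <- function(dd, rgr, dm_max, dm0, window) {
  tau <- f_dd_integral(dd, window)
  dm_max / (1 + (dm_max - dm0) / dm0 * exp(-rgr * tau))
}

#' Fit potential-growth parameters from organ-mass trajectories
#'
#' Extracts the upper envelope of the observed trajectories (90 percent
#' quantile per degree-day bin) and fits the logistic potential-growth
#' curve (imbalance and water-stress factors at 1) for the initial relative
#' growth rate, the maximal dry mass and the initial mass, by Nelder-Mead
#' least squares on log-parameters.
#'
#' @param dd degree-days of each observation.
#' @param dm observed organ dry masses, g.
#' @param window list with \code{dd0}, \code{dd_min}, \code{dd_max}
#'   (held fixed).
#' @param bin_width degree-day bin width for the quantile envelope.
#' @param quantile envelope quantile (default 0.9).
#' @return list with \code{rgr_ini}, \code{dm_max}, \code{dm0}, the
#'   envelope table, the objective value and the optim convergence code.
#' @export
fit_potential_growth <- function(dd, dm, window, bin_width = 100,
                                 quantile = 0.9) {
  stopifnot(length(dd) == length(dm), length(dd) >= 10)
  bin <- floor(dd / bin_width)
  env_dm <- as.numeric(tapply(dm, bin, stats::quantile, probs = quantile,
                              names = FALSE))
  env_dd <- as.numeric(tapply(dd, bin, mean))   # representative dd per bin
  sse <- function(theta) {
    pred <- potential_growth_curve(env_dd, exp(theta[1]), exp(theta[2]),
                                   exp(theta[3]), window)
    sum((env_dm - pred)^2)
  }
  start <- c(log(2 / max(f_dd_integral(max(dd), window), 1)),
             log(max(env_dm) * 1.2), log(max(min(env_dm), 1e-3)))
  fit <- stats::optim(start, sse, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  fit2 <- stats::optim(fit$par, sse, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-14))
  if (fit2$value > sse(start))
    warning("potential-growth fit did not improve on the start values")
  list(rgr_ini = exp(fit2$par[1]), dm_max = exp(fit2$par[2]),
       dm0 = exp(fit2$par[3]),
       envelope = data.frame(dd = env_dd, dm = env_dm),
       value = fit2$value, convergence = fit2$convergence)
}

# simulated long-format table matching an observation layout
sim_observation_table <- function(result, obs_dates) {
  fd <- result$fu_daily
  idx <- match(as.Date(obs_dates), as.Date(fd$dates))
  if (any(is.na(idx))) stop("observation dates outside the simulated season")
  n <- nrow(fd$leafy)
  rows <- list()
  for (j in seq_along(idx)) {
    rows[[length(rows) + 1]] <- data.frame(
      fu_id = seq_len(n), date = obs_dates[j], variable = "leafy",
      value = fd$leafy[, idx[j]])
    rows[[length(rows) + 1]] <- data.frame(
      fu_id = seq_len(n), date = obs_dates[j], variable = "fruit",
      value = fd$fruit[, idx[j]])
    rows[[length(rows) + 1]] <- data.frame(
      fu_id = 0L, date = obs_dates[j], variable = "ws",
      value = fd$ws[idx[j]])
  }
  do.call(rbind, rows)
}

#' Generate a pseudo-observation set from a simulation
#'
#' Samples the simulated per-unit leafy-shoot and fruit dry masses and the
#' water-sprout pool at the given dates, optionally with multiplicative
#' noise: the synthetic analogue of a field monitoring campaign, used for
#' parameter-recovery experiments.
#'
#' @param result a \code{season_result}.
#' @param obs_dates dates to sample (must be simulated dates).
#' @param noise_cv coefficient of variation of multiplicative Gaussian
#'   noise (0 for noise-free).
#' @param seed seed for the noise.
#' @param fu_ids optional subset of unit ids to keep (fruiting units).
#' @return long-format observation data frame for \code{criterion_a}.
#' @export
simulated_observations <- function(result, obs_dates, noise_cv = 0,
                                   seed = 1, fu_ids = NULL) {
  obs <- sim_observation_table(result, obs_dates)
  if (!is.null(fu_ids))
    obs <- obs[obs$fu_id %in% c(0L, fu_ids) | obs$variable == "ws", ]
  if (noise_cv > 0) {
    set.seed(as.integer(seed))
    obs$value <- obs$value * (1 + stats::rnorm(nrow(obs), 0, noise_cv))
  }
  obs
}

#' Fit the growth-reduction water-potential thresholds
#'
#' Global calibration of the two thresholds of the vegetative growth
#' reduction function by running the full season simulator and minimizing
#' the weighted criterion against observed leafy-shoot, water-sprout and
#' fruit dry masses. Derivative-free Nelder-Mead search on a logistic
#' reparameterization enforcing psi_min < psi_max < 0, with seeded
#' multi-start.
#'
#' @param obs long-format observation table (see \code{criterion_a}).
#' @param tree,forcing,params simulation inputs (hypothesis "both").
#' @param starts number of Nelder-Mead starts.
#' @param seed seed for the start points.
#' @param maxit maximum iterations per start.
#' @param reltol relative convergence tolerance.
#' @param restarts maximum incumbent restarts per start (each re-expands the
#'   Nelder-Mead simplex around the best point found so far).
#' @return list with \code{psi_min}, \code{psi_max}, \code{value} (best
#'   criterion), \code{trace} (per-start data frame) and \code{evals}.
#' @export
fit_psi_thresholds <- function(obs, tree, forcing, params = default_params(),
                               starts = 5, seed = 1, maxit = 40,
                               reltol = 1e-4, restarts = 2) {
  obs_dates <- unique(obs$date)
  evals <- 0L
  unpack <- function(theta) {
    psi_min <- -3.5 + 3 * stats::plogis(theta[1])
    psi_max <- psi_min + (-0.05 - psi_min) * stats::plogis(theta[2])
    c(psi_min, psi_max)
  }
  objective <- function(theta) {
    p <- unpack(theta)
    pr <- modify_params(params, list(growth = list(psi_min = p[1],
                                                   psi_max = p[2])))
    evals <<- evals + 1L
    res <- tryCatch(simulate_season(tree, forcing, pr, "both"),
                    error = function(e) NULL)
    if (is.null(res)) return(1e6)
    criterion_a(obs, sim_observation_table(res, obs_dates))
  }
  set.seed(as.integer(seed))
  th0 <- rbind(c(0, 0),
               matrix(stats::rnorm(2 * (starts - 1), 0, 1.2),
                      ncol = 2))
  trace <- data.frame()
  best <- NULL
  for (s in seq_len(starts)) {
    fit <- stats::optim(th0[s, ], objective, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = reltol))
    # restart around the incumbent: the collapsed simplex re-expands
    if (restarts > 0) for (r in seq_len(restarts)) {
      fit2 <- stats::optim(fit$par, objective, method = "Nelder-Mead",
                           control = list(maxit = maxit, reltol = reltol))
      improved <- fit2$value < fit$value * (1 - 1e-8)
      fit <- fit2
      if (!improved) break
    }
    p <- unpack(fit$par)
    trace <- rbind(trace, data.frame(start = s, psi_min = p[1],
                                     psi_max = p[2], value = fit$value,
                                     convergence = fit$convergence))
    if (is.null(best) || fit$value < best$value)
      best <- list(par = fit$par, value = fit$value)
  }
  if (is.null(best)) stop("all optimization starts failed")
  p <- unpack(best$par)
  list(psi_min = p[1], psi_max = p[2], value = best$value, trace = trace,
       evals = evals)
}

#' Fit the sugar sub-model parameters
#'
#' Nelder-Mead least squares of the four-pool sugar system against observed
#' pool trajectories, given the carbon influx and fruit relative growth
#' rate series of the simulation that produced (or accompanies) the
#' observations. The phloem sucrose share is constrained to [0, 1] and the
#' rates to be non-negative via log/logistic reparameterization.
#'
#' @param obs data frame with columns \code{t} (days), \code{variable}
#'   (\code{sucrose}, \code{sorbitol}, \code{glucose}, \code{fructose}) and
#'   \code{value} (pool carbon, g C).
#' @param influx,rgr daily series (day 1 .. max t) of flesh carbon influx
#'   (g C day-1) and fruit relative growth rate (day-1).
#' @param pools0 initial pools (named list, g C).
#' @param params starting sugar block (also supplies the fixed settings).
#' @param maxit,reltol Nelder-Mead settings.
#' @param starts number of jittered Nelder-Mead starts (the first is the
#'   supplied parameter block itself).
#' @param seed seed for the start-point jitter.
#' @return list with the fitted \code{params} (sugar block), \code{value}
#'   (residual sum of squares) and \code{convergence}.
#' @export
fit_sugar_params <- function(obs, influx, rgr, pools0,
                             params = default_params()$sugar,
                             maxit = 500, reltol = 1e-6, starts = 5,
                             seed = 1) {
  stopifnot(length(influx) == length(rgr))
  tmax <- max(obs$t)
  predict_pools <- function(sp) {
    pools <- lapply(pools0, function(x) x)
    out <- list()
    for (d in seq_len(tmax)) {
      st <- sugar_step(pools, influx[min(d, length(influx))],
                       rgr[min(d, length(rgr))], t = d - 1, dt = 1,
                       params = sp)
      pools <- st$pools
      out[[d]] <- pools
    }
    out
  }
  sse <- function(theta) {
    sp <- params
    sp$k1 <- stats::plogis(theta[1])
    sp$K3 <- exp(theta[2]); sp$K5 <- exp(theta[3])
    sp$K2_1 <- exp(theta[4]); sp$K2_2 <- theta[5]
    sp$K4_1 <- exp(theta[6])
    pred <- predict_pools(sp)
    tot <- 0
    for (r in seq_len(nrow(obs))) {
      p <- pred[[obs$t[r]]][[as.character(obs$variable[r])]]
      tot <- tot + (obs$value[r] - p)^2
    }
    tot
  }
  start <- c(stats::qlogis(min(max(params$k1, 1e-3), 1 - 1e-3)),
             log(params$K3), log(params$K5), log(params$K2_1),
             params$K2_2, log(params$K4_1))
  set.seed(as.integer(seed))
  starts_m <- rbind(start,
                    matrix(rep(start, each = starts - 1), starts - 1) +
                      cbind(matrix(stats::rnorm(4 * (starts - 1), 0, 0.5),
                                   starts - 1, 4),
                            stats::rnorm(starts - 1, 0, 8),
                            stats::rnorm(starts - 1, 0, 0.5)))
  fit <- NULL
  for (s in seq_len(nrow(starts_m))) {
    f1 <- stats::optim(starts_m[s, ], sse, method = "Nelder-Mead",
                       control = list(maxit = maxit, reltol = reltol))
    # restart around the incumbent: a collapsed 6-parameter simplex
    # usually re-expands to a better vertex
    for (r in 1:4) {
      f2 <- stats::optim(f1$par, sse, method = "Nelder-Mead",
                         control = list(maxit = maxit, reltol = reltol))
      improved <- f2$value < f1$value * (1 - 1e-10)
      f1 <- f2
      if (!improved) break
    }
    if (is.null(fit) || f1$value < fit$value) fit <- f1
  }
  out <- params
  out$k1 <- stats::plogis(fit$par[1])
  out$K3 <- exp(fit$par[2]); out$K5 <- exp(fit$par[3])
  out$K2_1 <- exp(fit$par[4]); out$K2_2 <- fit$par[5]
  out$K4_1 <- exp(fit$par[6])
  list(params = out, value = fit$value, convergence = fit$convergence)
}
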