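test_that("relative RMSE matches hand arithmetic and is scale invariant", {
  expect_equal(rrmse(c(5, 7, 9), c(5, 7, 9)), 0)
  expect_equal(rrmse(c(2, 4), c(3, 3)), (1 / 3))
  set.seed(2)
  obs <- runif(20, 1, 5); sim <- obs + rnorm(20, 0, 0.3)
  expect_equal(rrmse(obs, sim), rrmse(3.7 * obs, 3.7 * sim))
  expect_error(rrmse(c(-1, 1), c(0, 0)), "zero")
})

toy_obs <- function() {
  # 2 FUs x 2 dates x 3 variables, easy spreadsheet numbers
  expand.grid(fu_id = 1:2, date = as.Date("2011-07-01") + c(0, 14),
              variable = c("leafy", "ws", "fruit"),
              KEEP.OUT.ATTRS = FALSE)
}

test_that("the global criterion reproduces a spreadsheet computation", {
  obs <- toy_obs()
  obs$value <- c(10, 12, 14, 16,   2, 3, 4, 5,   20, 22, 24, 26)
  sim <- obs
  sim$value <- obs$value + c(1, -1, 2, 0,  0.5, 0, -0.5, 1,  3, 0, 0, -3)
  # spreadsheet: per variable, mean over dates within FU, mean over FUs,
  # divided by the variance of the observed values
  hand <- 0
  for (v in c("leafy", "ws", "fruit")) {
    o <- obs[obs$variable == v, ]; s <- sim[sim$variable == v, ]
    sq <- (o$value - s$value)^2
    per_fu <- tapply(sq, o$fu_id, mean)
    hand <- hand + mean(per_fu) / var(o$value)
  }
  expect_equal(criterion_a(obs, sim), hand, tolerance = 1e-12)
  # perfect fit
  expect_equal(criterion_a(obs, obs), 0)
  # invariance to row ordering
  perm <- sample(nrow(obs))
  expect_equal(criterion_a(obs[perm, ], sim), criterion_a(obs, sim))
  # single variable with every error equal to its sd -> that term is ~1
  o1 <- obs[obs$variable == "leafy", ]
  s1 <- o1; s1$value <- o1$value - sd(o1$value)
  expect_equal(criterion_a(o1, s1), 1, tolerance = 1e-12)
})

test_that("potential-growth parameters are recovered from clean envelopes", {
  gp <- default_params()$growth$leafy
  win <- list(dd0 = gp$dd0, dd_min = gp$dd_min, dd_max = gp$dd_max)
  dd <- seq(50, 2500, by = 50)
  # oracle data: high-accuracy ODE integration of the growth law
  # (independent of the closed form used by the fitting routine)
  rhs <- function(t, y, p) list(p$rgr * f_dd(t, win) * y *
                                  (1 - y / p$dm_max))
  sol <- deSolve::ode(c(dm = 0.4), times = c(0, dd), rhs,
                      parms = list(rgr = 0.002, dm_max = 4.65),
                      rtol = 1e-12, atol = 1e-12)
  dm_true <- sol[-1, "dm"]
  fit <- fit_potential_growth(dd, dm_true, win, bin_width = 50)
  expect_equal(fit$rgr_ini, 0.002, tolerance = 5e-4)
  expect_equal(fit$dm_max, 4.65, tolerance = 5e-4)
  # envelope of constant data is the constant
  cst <- fit_potential_growth(dd, rep(3, length(dd)), win)
  expect_equal(max(cst$envelope$dm), 3)
  expect_equal(min(cst$envelope$dm), 3)
})

test_that("noisy envelopes still recover the growth rate within 10%", {
  gp <- default_params()$growth$leafy
  win <- list(dd0 = 0, dd_min = 0, dd_max = 2500)
  set.seed(17)
  dd <- runif(200, 0, 2500)
  tau <- orchardsim:::f_dd_integral(dd, win)
  dm_clean <- 4.65 / (1 + (4.65 - 0.4) / 0.4 * exp(-0.002 * tau))
  dm_noisy <- dm_clean * (1 + rnorm(200, 0, 0.05))
  fit <- fit_potential_growth(dd, dm_noisy, win, bin_width = 100,
                              quantile = 0.5)
  expect_lt(abs(fit$rgr_ini - 0.002) / 0.002, 0.10)
})

test_that("sugar parameters are recovered from clean trajectories", {
  truth <- default_params()$sugar
  truth$dt <- 0.5                  # half-day integration for this study
  pools0 <- list(sucrose = 0.05, sorbitol = 0.05, glucose = 0.02,
                 fructose = 0.02)
  days <- 60
  set.seed(5)
  influx <- pmax(0.02 + cumsum(rnorm(days, 0, 0.002)), 0.005)
  rgr <- pmax(0.05 * exp(-seq_len(days) / 60), 1e-3)
  pools <- pools0; traj <- list()
  for (d in seq_len(days)) {
    st <- sugar_step(pools, influx[d], rgr[d], t = d - 1, dt = 1,
                     params = truth)
    pools <- st$pools
    traj[[d]] <- pools
  }
  keep <- seq(6, days, by = 6)
  obs <- do.call(rbind, lapply(keep, function(d) data.frame(
    t = d, variable = names(truth$cf), value = sapply(names(truth$cf),
      function(s) traj[[d]][[s]]))))
  start <- truth
  start$k1 <- 0.45; start$K3 <- 0.08; start$K5 <- 0.04
  start$K2_1 <- 0.06; start$K2_2 <- 65; start$K4_1 <- 3
  fit <- fit_sugar_params(obs, influx, rgr, pools0, params = start,
                          maxit = 500, starts = 2)
  expect_lt(fit$value, 1e-8)       # self-consistent optimum
  expect_lt(abs(fit$params$k1 - truth$k1), 0.02)
  # permuting the sugar labels destroys the fit
  obs_perm <- obs
  obs_perm$variable <- c(sucrose = "glucose", sorbitol = "fructose",
                         glucose = "sucrose",
                         fructose = "sorbitol")[obs$variable]
  sse_at <- function(o) fit_sugar_params(o, influx, rgr, pools0,
                                         params = truth, maxit = 1)$value
  expect_gt(sse_at(obs_perm), 100 * sse_at(obs))
})

test_that("the stress-threshold criterion is minimal at the true values", {
  tr <- synthetic_tree(9, n_fu = 4, n_fruits = 14, n_sprouts = 6)
  f <- generate_synthetic_forcing(8, days = 100, profile = "SS")
  r_true <- simulate_season(tr, f, hypothesis = "both")
  obs_dates <- f$dd$date[seq(30, 100, by = 10)]
  obs <- simulated_observations(r_true, obs_dates, noise_cv = 0)
  at <- function(psi_min, psi_max) {
    p <- default_params(growth = list(psi_min = psi_min, psi_max = psi_max))
    r <- simulate_season(tr, f, p, "both")
    criterion_a(obs, orchardsim:::sim_observation_table(r, obs_dates))
  }
  a_truth <- at(-1.949, -1.378)
  expect_lt(a_truth, 1e-12)                      # self-consistency
  expect_lt(a_truth, at(-3, -0.5))               # optimality at the truth
})
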