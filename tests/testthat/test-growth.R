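gp <- default_params()$growth

test_that("degree-day window factor is the exact piecewise form", {
  expect_equal(f_dd(900, gp$water_sprout), 0)     # before sprout emergence
  expect_equal(f_dd(1000, gp$leafy), 0.6)         # (2500-1000)/2500
  expect_equal(f_dd(gp$leafy$dd_max, gp$leafy), 0)
  expect_equal(f_dd(1000, gp$fruit), 1)           # inside the fruit window
  expect_equal(f_dd(2800, gp$fruit), 0)
  expect_equal(f_dd(2700, gp$fruit), 0.5)
})

test_that("growth reduction function is 0/linear/1 across the thresholds", {
  expect_equal(f_psi(-1.949), 0)
  expect_equal(f_psi(-2.5), 0)
  expect_equal(f_psi(-1.378), 1)
  expect_equal(f_psi(-0.5), 1)
  expect_equal(f_psi(-1.6635), 0.5, tolerance = 1e-3)
})

test_that("piecewise factors agree with symbolic evaluation at random points", {
  set.seed(7)
  psi <- runif(1e6, -4, 0)
  direct <- pmin(1, pmax(0, (psi + 1.949) / (1.949 - 1.378)))
  expect_equal(f_psi(psi), direct, tolerance = 1e-12)
  dd <- runif(1e6, 0, 3000)
  w <- gp$water_sprout
  direct_dd <- ifelse(dd < w$dd0, 0,
               ifelse(dd < w$dd_min, 1,
               ifelse(dd < w$dd_max, (w$dd_max - dd) / (w$dd_max - w$dd_min),
                      0)))
  expect_equal(f_dd(dd, w), direct_dd, tolerance = 1e-12)
})

test_that("potential growth step follows the logistic thermal-time form", {
  # leafy shoot, 2 g, balanced tree, one degree-day
  expect_equal(potential_growth_step(2, 1, 1, 1, 1, gp$leafy),
               0.00036 * 2 * (1 - 2 / 4.65), tolerance = 1e-12)
  # ceiling at Im-scaled maximal mass
  expect_equal(potential_growth_step(4.65 * 0.8, 1, 0.8, 1, 1, gp$leafy), 0)
  # multiplicative water-stress shutdown
  expect_equal(potential_growth_step(2, 10, 1, 1, 0, gp$leafy), 0)
  expect_error(potential_growth_step(2, 1, 1, 1, 1,
                                     list(rgr_ini = 1, dm_max = 0)),
               "positive")
})

test_that("fruit demand uses its own window with no water-stress factor", {
  expect_equal(fruit_demand_step(35, 1, 1000), 0)   # at the ceiling
  expect_equal(fruit_demand_step(10, 1, 1000),
               0.0025 * 10 * (1 - 10 / 35), tolerance = 1e-12)
  expect_equal(fruit_demand_step(10, 1, 2900), 0)   # past dd_max
})

test_that("distance-decay allocation distributes per demand and distance", {
  # equal distances: proportional to demands
  a <- allocate_carbon(1, c(2, 1), matrix(1, 1, 2), h = 1)
  expect_equal(a$received, c(2 / 3, 1 / 3))
  # 1 source, sinks at distance 1 and 2, equal demand, h = 1 -> 2/3 vs 1/3
  a2 <- allocate_carbon(1, c(1, 1), matrix(c(1, 2), 1, 2), h = 1)
  expect_equal(a2$received, c(2 / 3, 1 / 3))
  # sufficient supply satisfies every demand exactly
  a3 <- allocate_carbon(c(3, 2), c(1.2, 0.5, 1.1),
                        matrix(runif(6, 0.5, 3), 2, 3), h = 1.5)
  expect_equal(a3$received, c(1.2, 0.5, 1.1), tolerance = 1e-9)
  expect_equal(sum(a3$leftover), 5 - 2.8, tolerance = 1e-9)
  expect_error(allocate_carbon(1, 1, matrix(1), h = -1), ">= 0")
})

test_that("allocation conserves carbon and respects caps under scarcity", {
  set.seed(11)
  for (i in 1:20) {
    ns <- sample(2:5, 1); nk <- sample(2:6, 1)
    supply <- runif(ns, 0, 2); demand <- runif(nk, 0, 2)
    dist <- matrix(runif(ns * nk, 0.1, 5), ns, nk)
    a <- allocate_carbon(supply, demand, dist, h = 1)
    expect_true(all(a$received <= demand + 1e-9))
    expect_true(all(a$leftover >= -1e-12))
    expect_equal(sum(a$alloc) + sum(a$leftover), sum(supply),
                 tolerance = 1e-9)
    expect_equal(colSums(a$alloc), a$received, tolerance = 1e-12)
  }
})

test_that("imbalance is 1 at the target shoot:root ratio and clamped", {
  al <- default_params()$allocation
  expect_equal(tree_imbalance(100, 20, al), 1)
  expect_equal(tree_imbalance(1000, 20, al), 5)    # clamped high
  expect_equal(tree_imbalance(1, 1000, al), 0.2)   # clamped low
})

budget_fixture <- function(n_fu = 4, seed = 1) {
  set.seed(seed)
  state <- list(reserves = c(old_wood = 50, coarse_root = 25, fine_root = 2),
                old_wood_dm = 3000, coarse_root_dm = 1500, fine_root_dm = 30)
  dist_veg <- matrix(runif(n_fu * (n_fu + 2), 0.1, 3), n_fu, n_fu + 2)
  dist_fruit <- matrix(runif(n_fu * n_fu, 0.1, 3), n_fu, n_fu)
  list(state = state, dist_veg = dist_veg, dist_fruit = dist_fruit)
}

test_that("maintenance from reserves leaves masses unchanged", {
  fx <- budget_fixture()
  maint <- c(leafy = 0.4, fruit = 0.6)
  bud <- daily_carbon_budget(fx$state, assim = rep(0, 4), maint = maint,
                             demand_veg = rep(0.2, 6),
                             demand_fruit = rep(0.3, 4),
                             fx$dist_veg, fx$dist_fruit)
  expect_equal(sum(bud$growth_veg), 0)
  expect_equal(sum(bud$growth_fruit), 0)
  expect_equal(sum(fx$state$reserves) - sum(bud$reserves), 1.0)
  expect_equal(bud$starvation, 0)
  expect_lt(abs(bud$ledger$residual), 1e-12)
})

test_that("unpayable maintenance is a logged starvation, not an error", {
  fx <- budget_fixture()
  fx$state$reserves <- c(old_wood = 0.1, coarse_root = 0, fine_root = 0)
  bud <- daily_carbon_budget(fx$state, assim = rep(0.01, 4),
                             maint = c(leafy = 5),
                             demand_veg = rep(0.2, 6),
                             demand_fruit = rep(0.3, 4),
                             fx$dist_veg, fx$dist_fruit)
  expect_gt(bud$starvation, 0)
  expect_equal(sum(bud$growth_veg) + sum(bud$growth_fruit), 0)
})

test_that("the daily carbon ledger closes on random seeded days", {
  for (s in 1:100) {
    fx <- budget_fixture(seed = s)
    set.seed(s + 1000)
    assim <- runif(4, 0, 3)
    maint <- c(leafy = runif(1, 0, 1), fruit = runif(1, 0, 1),
               wood = runif(1, 0, 0.5))
    bud <- daily_carbon_budget(fx$state, assim, maint,
                               demand_veg = runif(6, 0, 0.8),
                               demand_fruit = runif(4, 0, 1.5),
                               fx$dist_veg, fx$dist_fruit)
    rel <- abs(bud$ledger$residual) /
      max(bud$ledger$assim + bud$ledger$draw, 1e-9)
    expect_lt(rel, 1e-9)
  }
})

test_that("vegetative sinks are served before fruit sinks", {
  fx <- budget_fixture()
  # supply covers vegetative demand but only part of fruit demand
  bud <- daily_carbon_budget(fx$state, assim = rep(0.5, 4), maint = c(m = 0),
                             demand_veg = rep(0.2, 6),
                             demand_fruit = rep(3, 4),
                             fx$dist_veg, fx$dist_fruit)
  cost <- default_params()$respiration$growth_cost
  expect_equal(sum(bud$growth_veg), 1.2, tolerance = 1e-9)  # fully met
  expect_lt(sum(bud$growth_fruit), 12)
  expect_equal(sum(bud$growth_veg) * (1 + cost) +
                 sum(bud$growth_fruit) * (1 + cost), 2, tolerance = 1e-9)
})
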