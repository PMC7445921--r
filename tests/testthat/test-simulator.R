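test_that("nothing moves without shipments or demand", {
  cfg <- scenario_config(
    links = dplyr::bind_rows(
      link_params("M", "P", tau = 60, n = 180),
      link_params("P", "W", tau = 15, n = 60),
      link_params("W", "H", tau = 3, n = 14)
    ),
    demand = demand_constant(0),
    initial_stocks = c(P = 100, W = 50, H = 25),
    horizon = 200
  )
  traj <- simulate_scenario(cfg)
  expect_equal(unique(traj$series$Y_P), 100)
  expect_equal(unique(traj$series$Y_W), 50)
  expect_equal(unique(traj$series$Y_H), 25)
  expect_identical(mass_balance(traj), 0)
})

test_that("transport delays shift stock rises by exactly tau", {
  # M -> P: dispatch day 120, tau 60 -> Y_P rises on day 180
  cfgP <- scenario_config(
    links = link_params("M", "P", tau = 60, n = 180, r0 = 120),
    demand = demand_constant(0),
    initial_stocks = c(P = 100), horizon = 250
  )
  trP <- simulate_scenario(cfgP, dispatch_plan = list(MP = discrete_shipment(100, 120)))
  expect_equal(first_rise_day(trP, "P"), 180)

  # P -> W: dispatch day 120, tau 15 -> Y_W rises on day 135
  cfgW <- scenario_config(
    links = link_params("P", "W", tau = 15, n = 60, r0 = 120),
    demand = demand_constant(0),
    initial_stocks = c(P = 500, W = 100), horizon = 250
  )
  trW <- simulate_scenario(cfgW, dispatch_plan = list(PW = discrete_shipment(100, 120)))
  expect_equal(first_rise_day(trW, "W"), 135)

  # logged arrivals always sit at dispatch + tau
  base <- simulate_scenario(fixture_scenario("baseline"))
  tau <- c(MP = 60, PW = 15, WH = 3)
  expect_equal(base$shipments$arrival_day,
               base$shipments$dispatch_day + tau[base$shipments$link],
               ignore_attr = TRUE)
})

test_that("stocks never go negative and unmet demand records the shortfall", {
  traj <- simulate_scenario(fixture_scenario("baseline"))
  s <- traj$series
  expect_true(all(s$Y_P >= 0 & s$Y_W >= 0 & s$Y_H >= 0))
  expect_gt(traj$totals$unmet, 0) # baseline is undersupplied at facilities
  # dispensed + unmet = total demand
  expect_equal(traj$totals$dispensed + traj$totals$unmet, 4 * 365,
               tolerance = 1e-9)
})

test_that("mass balance closes on every fixture and exactly for discrete runs", {
  for (name in c("baseline", "tracking", "seasonal")) {
    traj <- simulate_scenario(fixture_scenario(name))
    expect_lte(mass_balance(traj),
               1e-6 * max(traj$totals$dispatched[["MP"]], 1))
  }
  # discrete shipments, zero demand: residual exactly 0
  cfg <- wh_scenario(tau = 3, n = 20, stocks = c(W = 300, H = 0), horizon = 80)
  traj <- simulate_scenario(
    cfg, dispatch_plan = list(WH = discrete_shipment(c(50, 25), c(10, 30)))
  )
  expect_identical(mass_balance(traj), 0)
})

test_that("oversized dispatches are clipped to sender stock and flagged", {
  cfg <- wh_scenario(tau = 3, n = 20, stocks = c(W = 30, H = 0), horizon = 40)
  plan <- list(WH = discrete_shipment(100, 10))
  traj <- simulate_scenario(cfg, dispatch_plan = plan)
  expect_true(traj$shipments$clipped)
  expect_equal(traj$shipments$delivered, 30)
  expect_equal(max(traj$series$Y_H), 30)
  expect_identical(mass_balance(traj), 0)
  expect_error(simulate_scenario(cfg, dispatch_plan = plan, strict_clipping = TRUE),
               "exceeds")
})

test_that("the shipment-balance condition holds iff pulse mass matches demand", {
  c0 <- 4
  n <- 14
  lk <- link_params("W", "H", tau = 3, n = n, A = c0 * n / sqrt(pi), B = 1, r0 = 8)
  res <- check_steady_state(lk, demand_constant(c0))
  expect_true(res$holds)
  expect_equal(res$lhs, res$rhs)

  lk0 <- lk
  lk0$A <- 0
  expect_false(check_steady_state(lk0, demand_constant(c0))$holds)
})

test_that("balanced shipments give an n-periodic facility stock; surplus accumulates", {
  c0 <- 4
  n <- 14
  lk <- link_params("W", "H", tau = 3, n = n, A = c0 * n / sqrt(pi), B = 1, r0 = 8)
  cfg <- scenario_config(lk, demand_constant(c0), c(W = 5000, H = 100),
                         horizon = 200, dt = 0.05, sample_every = 1)
  traj <- simulate_scenario(cfg)
  s <- traj$series
  first_arrival <- min(traj$shipments$arrival_day)
  post <- which(s$t >= first_arrival + 6 & s$t <= traj$horizon - n)
  dev <- max(abs(s$Y_H[post] - s$Y_H[post + n]))
  expect_lt(dev, 0.01 * c0 * n) # within 1% of one shipment size

  # 10% surplus on the left side: period-over-period minima strictly increase
  lks <- lk
  lks$A <- lk$A * 1.1
  cfgs <- scenario_config(lks, demand_constant(c0), c(W = 5000, H = 100),
                          horizon = 200, dt = 0.05, sample_every = 1)
  ss <- simulate_scenario(cfgs)$series
  mins <- vapply(seq(20, 180, by = n), function(a) {
    min(ss$Y_H[ss$t >= a & ss$t < a + n])
  }, numeric(1))
  expect_true(all(diff(mins) > 0))
})

test_that("halving the step shrinks the discretization error", {
  run <- function(dt) {
    lk <- link_params("W", "H", tau = 2.7, n = 17.3, A = 30 / sqrt(pi), B = 1,
                      r0 = 10.3)
    cfg <- scenario_config(lk, demand_constant(3), c(W = 500, H = 30),
                           horizon = 60, dt = dt, sample_every = 1)
    simulate_scenario(cfg)$series$Y_H
  }
  y1 <- run(0.2)
  y2 <- run(0.1)
  y3 <- run(0.05)
  d1 <- max(abs(y1 - y2))
  d2 <- max(abs(y2 - y3))
  expect_gt(d1, 0)
  expect_lte(d2, 0.75 * d1 + 1e-9)
})

test_that("resampling point-samples stocks and preserves flow integrals", {
  cfg <- fixture_scenario("baseline", dt = 0.1, sample_every = 0.1)
  fine <- simulate_scenario(cfg)
  same <- resample_trajectory(fine, 0.1)
  expect_identical(same$series, fine$series)

  daily <- resample_trajectory(fine, 1)
  days <- daily$series$t
  expect_equal(daily$series$Y_H,
               fine$series$Y_H[match(days, fine$series$t)])
  # window-averaged flows integrate to the fine-grid totals
  expect_equal(sum(daily$series$F_WH) * 1, sum(fine$series$F_WH) * 0.1,
               tolerance = 1e-9)
  expect_equal(sum(daily$series$unmet) * 1, sum(fine$series$unmet) * 0.1,
               tolerance = 1e-9)
  expect_error(resample_trajectory(fine, 0.05), "finer")
})
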