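test_that("decision days and forecasting windows follow the worked arithmetic", {
  lk <- link_params("W", "H", tau = 3, n = 14, r0 = 28)
  ctl <- controller_params("W", "H", L = 50, d = 2)
  ds <- decision_schedule(lk, ctl, horizon = 60)
  # dispatch day 28: decided on day 26, window [26, 45] (next arrival day 45)
  expect_equal(ds$decision_day[1], 26)
  expect_equal(ds$window_start[1], 26)
  expect_equal(ds$window_end[1], 45)
  # one period later, shifted by n = 14
  expect_equal(ds$decision_day[2], 40)
  expect_equal(ds$window_end[2], 59)
  # zero lead time: decision day equals dispatch day
  ds0 <- decision_schedule(lk, controller_params("W", "H", L = 50, d = 0), 60)
  expect_equal(ds0$decision_day, ds0$dispatch_day)
})

test_that("forecast_stock projects at constant rate; order_size tops up to L", {
  # worked example: stock 100, demand 4, 19-day window -> 24; order 26
  p <- forecast_stock(100, numeric(), 4, c(26, 45))
  expect_equal(p, 24)
  expect_equal(order_size(p, 50), 26)
  # floor at zero and pure pipeline accumulation
  expect_equal(forecast_stock(0, numeric(), 9, c(0, 10)), 0)
  expect_equal(forecast_stock(10, data.frame(size = 50), 0, c(0, 10)), 60)
  # unfloored projection exposes the deficit
  expect_equal(forecast_stock(10, numeric(), 4, c(0, 20), floor = FALSE), -70)
  # demand model evaluated at the window start
  seas <- demand_seasonal(data.frame(start = c(0, 100), end = c(100, 200),
                                     rate = c(2, 8)))
  expect_equal(forecast_stock(100, numeric(), seas, c(99, 109)), 80)
  expect_equal(forecast_stock(100, numeric(), seas, c(100, 110)), 20)
  # order-up-to rule
  expect_equal(order_size(60, 50), 0)
  expect_equal(order_size(0, 0), 0)
})

test_that("closed loop holds facility stock at or above L_H under constant demand", {
  traj <- simulate_scenario(fixture_scenario("tracking"))
  fca <- first_controlled_arrival(traj)
  s <- traj$series
  expect_false(is.na(fca))
  expect_gte(min(s$Y_H[s$t >= fca]), 10)
  expect_identical(stockout_days(traj, c(fca, traj$horizon)), 0L)
  # zero-size decisions (stock still above L) are logged but dispatch nothing
  cfg_hi <- fixture_scenario("tracking")
  cfg_hi$initial_stocks["H"] <- 300
  hi <- simulate_scenario(cfg_hi)
  zero <- hi$decisions[hi$decisions$ordered == 0 & hi$decisions$link == "WH", ]
  expect_gt(nrow(zero), 0)
  expect_false(any(paste(hi$shipments$link, hi$shipments$dispatch_day) %in%
                     paste(zero$link, zero$dispatch_day)))
})

test_that("steady-cycle orders rediscover the shipment-balance size c*n", {
  traj <- simulate_scenario(fixture_scenario("tracking"))
  wh <- traj$decisions[traj$decisions$link == "WH", ]
  steady <- wh$ordered[wh$decision_day > 50]
  expect_true(all(abs(steady - 4 * 14) < 1e-6))
})

test_that("pipeline accounting prevents double ordering", {
  traj <- simulate_scenario(fixture_scenario("tracking"))
  d <- traj$decisions[traj$decisions$link == "WH", ]
  L <- 10
  for (win in list(c(0, 100), c(50, 200), c(100, 365))) {
    ordered <- sum(d$ordered[d$decision_day >= win[1] & d$decision_day < win[2]])
    demand_tot <- 4 * (win[2] - win[1])
    expect_lte(ordered, L + demand_tot + 4 * 14 + 1e-6)
  }
})

test_that("long-run facility stock stays in the expiry-guard band [L, L + c(n+tau)]", {
  traj <- simulate_scenario(fixture_scenario("tracking"))
  s <- traj$series
  late <- s$Y_H[s$t >= 150]
  avg <- mean(late)
  expect_gte(avg, 10)
  expect_lte(avg, 10 + 4 * (14 + 3))
})

test_that("raising L_H raises both the minimum and the mean facility stock", {
  run_L <- function(L) {
    cfg <- fixture_scenario("tracking")
    cfg$controller$L[cfg$controller$to == "H"] <- L
    s <- simulate_scenario(cfg)$series
    c(min = min(s$Y_H[s$t >= 30]), mean = mean(s$Y_H[s$t >= 30]))
  }
  lo <- run_L(10)
  hi <- run_L(40)
  expect_gt(hi[["min"]], lo[["min"]])
  expect_gt(hi[["mean"]], lo[["mean"]])
})

test_that("ample upstream stock yields all-zero upstream orders", {
  cfg <- fixture_scenario("tracking")
  cfg$initial_stocks["P"] <- 50000 # far above L_P
  traj <- simulate_scenario(cfg)
  mp <- traj$decisions[traj$decisions$link == "MP", ]
  expect_gt(nrow(mp), 0)
  expect_true(all(mp$ordered == 0))
  expect_false(any(traj$shipments$link == "MP"))
})

test_that("a demand step inside one window causes a single corrected dip", {
  traj <- simulate_scenario(fixture_scenario("seasonal"))
  fca <- first_controlled_arrival(traj)
  s <- traj$series
  below <- s$Y_H < 50 - 1e-6 & s$t >= fca
  runs <- rle(below)
  expect_identical(sum(runs$values), 1L)
  dip_days <- s$t[below]
  expect_true(all(dip_days >= 100)) # the dip follows the day-100 demand step
  # the next decision's arrival restores the level
  d <- traj$decisions
  fix <- d[d$link == "WH" & d$decision_day >= 100 & d$ordered > 0, ][1, ]
  arrival <- fix$dispatch_day + 3
  expect_equal(max(dip_days) + 1, arrival + traj$interval - 1, tolerance = 1)
  expect_gte(min(s$Y_H[s$t > arrival + 1]), 50)
})

test_that("raising the decision lead time never shrinks the post-step dip", {
  dip_for <- function(d_W) {
    cfg <- fixture_scenario("seasonal")
    cfg$controller$d[cfg$controller$from == "W"] <- d_W
    s <- simulate_scenario(cfg)$series
    max(0, 50 - min(s$Y_H[s$t >= 30]))
  }
  expect_gte(dip_for(5) + 1e-6, dip_for(2))
})

test_that("controller shipments can use the link's Gaussian pulse shape", {
  cfg <- fixture_scenario("tracking")
  traj <- simulate_scenario(cfg, controller_shipments = "gaussian")
  s <- traj$series
  fca <- first_controlled_arrival(traj)
  expect_gte(min(s$Y_H[s$t >= fca + 7]), 10 - 0.05 * 56)
  expect_lte(mass_balance(traj), 1e-6 * max(traj$totals$dispatched[["MP"]], 1))
})
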