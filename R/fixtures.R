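# Built-in study scenarios: a representative low-income-country chain with
# transport times 60/15/3 days, 180-day manufacturer cycles, 60-day
# procurer cycles and 14-day facility deliveries, plus a three-season
# demand year (high season from day 100, moderate from day 250). Values
# chosen once; rationale in the methods vignette.

#' Built-in scenario fixtures
#'
#' Three ready-made scenarios used throughout the documentation and tests:
#' * `"baseline"` — open loop. Transport times `tau_MP = 60`, `tau_PW = 15`,
#'   `tau_WH = 3` days; periodicities 180/60/14 days; Gaussian shipments
#'   sized 720/240/40 packages; constant demand 4 packages/day. Facility
#'   deliveries (40 pkgs) undercut per-cycle demand (56 pkgs), so recurrent
#'   stockouts build up — the motivating failure mode.
#' * `"tracking"` — the same chain with the digital-tracking controller on
#'   every link (`L_H = 10`, `L_W = 400`, `L_P = 1200`; lead times
#'   `d_W = 2`, `d_P = 5`, `d_M = 10` days).
#' * `"seasonal"` — controller plus a three-season demand year: low
#'   (4 pkgs/day) until day 100, high (10) until day 250, moderate (6) to
#'   day 365, with `L_H = 50`.
#'
#' @param name Fixture name.
#' @param dt Integration step in days.
#' @param sample_every Output sampling interval in days.
#' @return An `sc_scenario` that passes [validate_scenario()].
#' @examples
#' cfg <- fixture_scenario("tracking")
#' validate_scenario(cfg)
#' @export
fixture_scenario <- function(name = c("baseline", "tracking", "seasonal"),
                             dt = 0.05, sample_every = 1) {
  name <- match.arg(name)
  links <- dplyr::bind_rows(
    link_params("M", "P", tau = 60, n = 180, A = 720 / (3 * sqrt(pi)), B = 3, r0 = 120),
    link_params("P", "W", tau = 15, n = 60, A = 240 / (2 * sqrt(pi)), B = 2, r0 = 60),
    link_params("W", "H", tau = 3, n = 14, A = 40 / (1 * sqrt(pi)), B = 1, r0 = 8)
  )
  controller <- dplyr::bind_rows(
    controller_params("M", "P", L = 1200, d = 10),
    controller_params("P", "W", L = 400, d = 5),
    controller_params("W", "H", L = 10, d = 2)
  )
  switch(name,
    baseline = scenario_config(
      links = links,
      demand = demand_constant(4),
      initial_stocks = c(P = 1500, W = 800, H = 60),
      horizon = 365, dt = dt, sample_every = sample_every
    ),
    tracking = scenario_config(
      links = links,
      demand = demand_constant(4),
      initial_stocks = c(P = 1500, W = 800, H = 60),
      horizon = 365, dt = dt, sample_every = sample_every,
      controller = controller
    ),
    seasonal = {
      controller$L[controller$to == "H"] <- 50
      scenario_config(
        links = links,
        demand = demand_seasonal(tibble(
          start = c(0, 100, 250), end = c(100, 250, 365), rate = c(4, 10, 6)
        )),
        initial_stocks = c(P = 3000, W = 1200, H = 100),
        horizon = 365, dt = dt, sample_every = sample_every,
        controller = controller
      )
    }
  )
}

#' Intervention scenario set
#'
#' The baseline plus the four intervention transforms at illustrative
#' magnitudes: prevention halves demand, roads halve `tau_WH` (with the
#' default 1.1 size accompaniment), workforce halves the facility delivery
#' period, vehicles raise the facility shipment amplitude by 50%.
#'
#' @param dt,sample_every Passed to [fixture_scenario()].
#' @return Named list of `sc_scenario` objects
#'   (`baseline, prevention, roads, workforce, vehicles`).
#' @export
fixture_interventions <- function(dt = 0.05, sample_every = 1) {
  base <- fixture_scenario("baseline", dt = dt, sample_every = sample_every)
  list(
    baseline = base,
    prevention = apply_intervention(base, "prevention", factor = 0.5),
    roads = apply_intervention(base, "roads", factor = 0.5),
    workforce = apply_intervention(base, "workforce", factor = 0.5),
    vehicles = apply_intervention(base, "vehicles", factor = 1.5)
  )
}
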