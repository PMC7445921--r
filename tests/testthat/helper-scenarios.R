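# Small scenario builders shared across tests. Links that are absent carry
# no flow, so single-link chains isolate one compartment's dynamics.

wh_scenario <- function(A = 0, B = 0, r0 = 0, n = 14, tau = 3,
                        demand = demand_constant(0),
                        stocks = c(W = 1000, H = 100),
                        horizon = 100, dt = 0.05, sample_every = 1,
                        controller = NULL) {
  scenario_config(
    links = link_params("W", "H", tau = tau, n = n, A = A, B = B, r0 = r0),
    demand = demand,
    initial_stocks = stocks,
    horizon = horizon, dt = dt, sample_every = sample_every,
    controller = controller
  )
}

# A bare trajectory with a prescribed facility-stock series, for metric
# oracles that need hand-built inputs.
hand_trajectory <- function(Y_H, horizon = length(Y_H) - 1) {
  structure(
    list(
      series = tibble::tibble(
        t = seq_along(Y_H) - 1, Y_P = 0, Y_W = 0, Y_H = Y_H,
        F_MP = 0, F_PW = 0, F_WH = 0, D = 0, unmet = 0
      ),
      shipments = tibble::tibble(
        link = character(), dispatch_day = numeric(), arrival_day = numeric(),
        size = numeric(), delivered = numeric(), clipped = logical(),
        source = character()
      ),
      decisions = NULL,
      totals = list(dispatched = c(MP = 0, PW = 0, WH = 0),
                    arrived = c(MP = 0, PW = 0, WH = 0),
                    dispensed = 0, unmet = 0,
                    initial = c(P = 0, W = 0, H = Y_H[1]),
                    final = c(P = 0, W = 0, H = Y_H[length(Y_H)])),
      dt = 1, interval = 1, horizon = horizon, controller_used = FALSE
    ),
    class = "sc_trajectory"
  )
}
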