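# The digital-tracking forecasting controller. Each compartment's stock is
# projected to the end of a forecasting window and fed back to its supplier,
# which sizes the next scheduled shipment to push the stock back up to the
# desired level L (order-up-to policy). The window runs from the decision
# day (d days before the dispatch) to the arrival of the *following*
# shipment, because the shipment being sized must carry the compartment
# until that next arrival.

#' Decision schedule of a controlled link
#'
#' For each scheduled dispatch day `s` in `r0, r0 + n, ...` up to the
#' horizon: the decision day is `s - d` (floored at 0) and the forecasting
#' window spans from the decision day to `s + n + tau`, the arrival of the
#' next shipment. With the worked parameters tau = 3, n = 14, d = 2 and a
#' dispatch on day 28, the size is decided on day 26 and the window is
#' [26, 45].
#'
#' @param link One-row link tibble from [link_params()].
#' @param ctrl One-row controller tibble from [controller_params()]
#'   (`d <= n` required).
#' @param horizon Last admissible dispatch day.
#' @return Tibble `decision_day, dispatch_day, window_start, window_end`.
#' @examples
#' decision_schedule(
#'   link_params("W", "H", tau = 3, n = 14, r0 = 28),
#'   controller_params("W", "H", L = 50, d = 2),
#'   horizon = 60
#' )
#' @export
decision_schedule <- function(link, ctrl, horizon) {
  stopifnot(ctrl$d <= link$n)
  s <- if (link$r0 <= horizon) seq(link$r0, horizon, by = link$n) else numeric()
  tibble(
    decision_day = pmax(0, s - ctrl$d),
    dispatch_day = s,
    window_start = pmax(0, s - ctrl$d),
    window_end = s + link$n + link$tau
  )
}

#' Forecast a compartment's stock at the end of a window
#'
#' Projects the stock forward assuming the demand rate observed at the
#' window start stays constant throughout the window and no new shipment is
#' sent: current stock, plus pipeline (dispatched-but-unarrived) shipments
#' arriving inside the window, minus rate times window length.
#'
#' With `floor = TRUE` (the default) the projection is floored at 0 —
#' physical stock cannot go negative. The closed-loop engine sizes orders
#' from the *unfloored* projection instead: a negative value measures the
#' projected deficit, which the order must also cover for the order-up-to
#' policy to restore the desired level (see the methods vignette).
#'
#' @param stock Current stock in packages.
#' @param arrivals Pipeline arrivals landing inside the window: a numeric
#'   vector of sizes, or a data frame with a `size` column.
#' @param demand An `sc_demand` (evaluated at the window start) or a plain
#'   numeric rate in packages/day.
#' @param window Numeric `c(start, end)` in days, `end > start`.
#' @param floor Floor the projection at 0.
#' @return Predicted stock in packages at the window end.
#' @examples
#' forecast_stock(100, numeric(), 4, c(26, 45)) # 100 - 4*19 = 24
#' @export
forecast_stock <- function(stock, arrivals, demand, window, floor = TRUE) {
  stopifnot(length(window) == 2, window[2] > window[1])
  pipe <- if (is.data.frame(arrivals)) sum(arrivals$size) else sum(arrivals)
  rate <- if (inherits(demand, "sc_demand")) {
    demand_rate(demand, window[1])
  } else {
    as.numeric(demand)
  }
  out <- stock + pipe - rate * (window[2] - window[1])
  if (floor) out <- max(0, out)
  out
}

#' Size a shipment from the order-up-to rule
#'
#' The shipment must lift the predicted stock back to the desired level:
#' `max(0, L - predicted)`. A predicted stock already above `L` yields 0 —
#' no shipment is necessary.
#'
#' @param predicted Predicted stock at the window end, in packages (may be
#'   negative when the projection is unfloored).
#' @param L Desired stock level in packages (>= 0).
#' @return Shipment size in packages.
#' @examples
#' order_size(24, 50) # 26
#' order_size(60, 50) # 0
#' @export
order_size <- function(predicted, L) {
  stopifnot(all(L >= 0))
  pmax(0, L - predicted)
}

#' First arrival of a controller-ordered shipment
#'
#' Closed-loop stock guarantees hold only once the controller's first
#' shipment has landed; this locates that day in the shipment log.
#'
#' @param traj A closed-loop `sc_trajectory`.
#' @param link Link id, default `"WH"` (arrivals at health facilities).
#' @return Arrival day, or `NA` if the controller never shipped on the link.
#' @export
first_controlled_arrival <- function(traj, link = "WH") {
  sh <- traj$shipments
  sh <- sh[sh$link == link & sh$source == "controller", , drop = FALSE]
  if (!nrow(sh)) return(NA_real_)
  min(sh$arrival_day)
}
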