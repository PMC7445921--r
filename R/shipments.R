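# Shipment pulses. A shipment on a link is a Gaussian flow-rate pulse
# F(t) = A * exp(-(t - r)^2 / B^2): amplitude A (packages/day), width B
# (days; B is where F drops to A/e), peak time r. Its area — the shipment
# size — is A*B*sqrt(pi) packages. The discrete limit B -> 0 transfers the
# whole size instantaneously.

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Evaluate one Gaussian shipment pulse
#'
#' `A * exp(-(t - r)^2 / B^2)`, truncated to exactly zero beyond `K * B` days
#' from the peak so a pulse never leaks into unrelated periods. At the default
#' `K = 6` the discarded tail mass is below 1e-15 of the shipment size.
#'
#' @param t Time(s) in days.
#' @param A Amplitude in packages/day (>= 0).
#' @param B Width parameter in days (> 0; for `B = 0` use the discrete path,
#'   see [discrete_shipment()]).
#' @param r Peak time in days.
#' @param K Truncation constant (support is `|t - r| <= K * B`).
#' @return Flow rate(s) in packages/day.
#' @examples
#' pulse_value(120, A = 5, B = 2, r = 120) # peak value = A
#' pulse_value(2, A = 1, B = 2, r = 0)     # A * exp(-1)
#' @export
pulse_value <- function(t, A, B, r, K = 6) {
  stopifnot(A >= 0)
  if (!(B > 0)) {
    abort("B <= 0: use the discrete-shipment path (B = 0 is the discrete limit)")
  }
  out <- A * exp(-((t - r)^2) / B^2)
  out[abs(t - r) > K * B] <- 0
  out
}

#' Shipment size of one pulse
#'
#' The area under one Gaussian pulse: `A * B * sqrt(pi)` packages.
#'
#' @param A Amplitude in packages/day (>= 0).
#' @param B Width in days (>= 0; 0 gives size 0 — discrete shipments carry an
#'   explicit size instead).
#' @return Size in packages.
#' @examples
#' shipment_size(10, 1) # 10 * sqrt(pi)
#' @export
shipment_size <- function(A, B) {
  stopifnot(all(A >= 0), all(B >= 0))
  A * B * sqrt(pi)
}

# Exact mass of a (truncated) unit-size pulse between t0 and t1:
# the erf difference, with the argument clamped to [-K, K].
pulse_mass_fraction <- function(t0, t1, r, B, K = 6) {
  u0 <- pmin(pmax((t0 - r) / B, -K), K)
  u1 <- pmin(pmax((t1 - r) / B, -K), K)
  (erf(u1) - erf(u0)) / 2
}

#' Periodic pulse train on a link
#'
#' Dispatch peaks sit at `r0, r0 + n, r0 + 2n, ...` up to the horizon. Each
#' pulse's area equals its size: the default `A*B*sqrt(pi)`, or a per-shipment
#' override. An override rescales the amplitude with `B` fixed
#' (`A = size / (B*sqrt(pi))`): pulse duration is a property of the link,
#' size is a per-shipment decision. Zero-size pulses are dropped from the
#' dispatch list. Overlapping pulses sum — the flow is linear in
#' contributions.
#'
#' @param link One-row link tibble from [link_params()].
#' @param horizon Last admissible dispatch day (> 0).
#' @param sizes Optional numeric vector of per-shipment package overrides,
#'   recycled along the dispatch sequence.
#' @param K Truncation constant, see [pulse_value()].
#' @return An object of class `sc_pulse_train`: a list with `pulses`
#'   (tibble `dispatch_day, size, B`), `flow` (vectorized function of t,
#'   packages/day), and the generating `link`.
#' @examples
#' tr <- pulse_train(link_params("W", "H", 3, n = 14, A = 10, B = 1, r0 = 28),
#'                   horizon = 50)
#' tr$pulses$dispatch_day # 28, 42
#' @export
pulse_train <- function(link, horizon, sizes = NULL, K = 6) {
  stopifnot(horizon > 0)
  days <- if (link$r0 <= horizon) seq(link$r0, horizon, by = link$n) else numeric()
  size0 <- shipment_size(link$A, link$B)
  sz <- if (is.null(sizes)) rep(size0, length(days)) else rep_len(sizes, length(days))
  pulses <- tibble(dispatch_day = days, size = sz, B = link$B)
  pulses <- pulses[pulses$size > 0, , drop = FALSE]
  flow <- function(t) {
    out <- numeric(length(t))
    for (i in seq_len(nrow(pulses))) {
      if (pulses$B[i] > 0) {
        A_eff <- pulses$size[i] / (pulses$B[i] * sqrt(pi))
        out <- out + pulse_value(t, A_eff, pulses$B[i], pulses$dispatch_day[i], K = K)
      }
    }
    out
  }
  structure(list(pulses = pulses, flow = flow, link = link, K = K),
            class = "sc_pulse_train")
}

#' @export
print.sc_pulse_train <- function(x, ...) {
  cat("<sc_pulse_train>", link_id(x$link$from, x$link$to),
      "-", nrow(x$pulses), "dispatches\n")
  print(x$pulses, ...)
  invisible(x)
}

#' A discrete (instantaneous) shipment event
#'
#' The `B -> 0` limit of a pulse: removal of `size` packages from the sender
#' at the dispatch day and addition to the receiver `tau` days later, as step
#' changes. Integrating the event's flow over any window containing it yields
#' exactly `size`.
#'
#' @param size Packages (>= 0); a zero size produces no state change.
#' @param dispatch_day Day of departure.
#' @return One-row tibble `dispatch_day, size, B = 0`, usable inside a
#'   `dispatch_plan` for [simulate_scenario()].
#' @examples
#' discrete_shipment(50, 28)
#' @export
discrete_shipment <- function(size, dispatch_day) {
  stopifnot(all(size >= 0))
  tibble(dispatch_day = as.numeric(dispatch_day), size = as.numeric(size), B = 0)
}
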