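---
title: "Modelling essential-medicine supply chains with drugflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling essential-medicine supply chains with drugflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drugflow)
library(dplyr)
```

## The model

drugflow simulates the flow of a single, undifferentiated drug product
through the tiers of a national supply chain: manufacturers (M) ship to
procurers (P), procurers to warehouses (W), warehouses to health facilities
(H), and patients (R) collect from facilities. Stocks are tracked at P, W
and H; manufacturers are an unbounded source and recipients a pure sink.
The stock balances are

$$
\frac{dY_P}{dt} = F_{MP}(t-\tau_{MP}) - F_{PW}(t), \qquad
\frac{dY_W}{dt} = F_{PW}(t-\tau_{PW}) - F_{WH}(t), \qquad
\frac{dY_H}{dt} = F_{WH}(t-\tau_{WH}) - D(t),
$$

where each $F$ is the dispatch-side flow rate on a link, $\tau$ its
transport time, and $D(t)$ the patient demand rate. Units are fixed
globally: time in days, stock in packages, flows in packages/day. A
shipment is a Gaussian flow pulse
$F(t) = A\,e^{-(t-r)^2/B^2}$ with amplitude $A$, width $B$ (the duration of
loading/unloading; $F(r \pm B) = A/e$) and peak time $r$; its area — the
shipment size — is $A B \sqrt{\pi}$ packages. Shipments repeat every $n$
days. Letting $B \to 0$ gives discrete shipments: instantaneous removal of
the size at dispatch and addition at the receiver $\tau$ days later.

Because the delayed inflow terms are prescribed functions of time rather
than functions of the state, the system is ordinary quadrature with events,
not a state-dependent delay-differential problem. That is why the package
integrates with its own fixed-step scheme instead of a general ODE/DDE
solver: exactness of the discrete-shipment path and event-level control of
clipping matter more here than adaptive stepping (the system is non-stiff
by construction).

## Parameters that matter

| parameter | unit | meaning | fixture default |
|---|---|---|---|
| $\tau_{MP}, \tau_{PW}, \tau_{WH}$ | days | transport times | 60, 15, 3 |
| $n_{MP}, n_{PW}, n_{WH}$ | days | shipment periodicities | 180, 60, 14 |
| $A$, $B$ | pkgs/day, days | pulse amplitude and width per link | sized below |
| $r_0$ | day | first dispatch peak | 120, 60, 8 |
| $D(t)$ | pkgs/day | demand rate | 4 (constant form) |
| $L_P, L_W, L_H$ | pkgs | desired stock levels (controller) | 1200, 400, 10 |
| $d_M, d_P, d_W$ | days | decision lead times (controller) | 10, 5, 2 |
| `dt` | days | integration step | 0.05 |
| `truncation_k` | — | pulse support is $|t-r| \le K B$ | 6 |

Facility stock neither drains nor accumulates when the per-day shipment
mass balances mean demand over one cycle:

$$
\frac{A_{WH} B_{WH} \sqrt{\pi}}{n_{WH}} = \bar D, \qquad
\bar D = \frac{1}{n_{WH}} \int_{\tau_{WH}}^{\tau_{WH}+n_{WH}} D(t)\,dt .
$$

`check_steady_state()` evaluates both sides; the simulator tests confirm
that equality produces an $n$-periodic facility stock and that a 10%
surplus produces strictly growing period minima (stock-up / expiry risk).

## The forecasting controller

A digital tracking system turns the push schedule into an order-up-to
policy. For a dispatch scheduled on day $s$, the size is decided at
$s - d$; the forecasting window runs from the decision day to $s + n +
\tau$, the arrival of the *following* shipment, because the shipment being
sized must carry the compartment until then. The projection assumes the
demand rate observed on the decision day holds throughout the window, adds
pipeline (dispatched-but-unarrived) shipments landing inside the window,
and the order is $\max(0, L - \hat Y)$.

Three genuinely open points were resolved as follows:

* **Signed projections.** `forecast_stock()` floors the projection at zero
  by default — physical stock cannot be negative. The closed-loop engine,
  however, sizes orders from the *unfloored* projection: a negative value
  measures the projected deficit, and discarding it caps every order at
  $L$, which can never sustain a cycle consuming $c \cdot n > L$ packages.
  With the signed projection the policy is deadbeat under constant demand:
  after one decision, every pre-arrival trough equals $L$ exactly and every
  steady-cycle order equals $c \cdot n$ — the controller rediscovers the
  balance condition above. Both behaviours are asserted in the tests.
* **Pipeline inventory is counted.** Ignoring in-transit stock would
  double-order whenever $\tau + d$ overlaps the previous shipment's
  transit. A test asserts the resulting no-double-ordering bound. The
  assumption can be probed by passing `arrivals = numeric()` to
  `forecast_stock()`.
* **Upstream windows.** Warehouses and procurers use the same window rule
  with their own $L$ and $d$, and the facility demand rate at the decision
  day serves as the depletion proxy for upstream stocks — in steady state
  the mean outflow of every tier equals demand, and it is the only rate
  signal a tracking system observes directly.

Controller-ordered shipments are discrete transfers by default (sizes are
decided, durations are a link property); `controller_shipments =
"gaussian"` reuses the link's $B$.

## Numerical scheme

Fixed-step forward Euler with `dt = 0.05` day. Two refinements keep the
bookkeeping exact:

* Per-step outflow masses are analytic: erf differences for Gaussian
  pulses, whole-size steps for discrete events. Summed over a pulse's
  support these telescope to the full shipment size.
* The receiver's inflow replays the sender's *actual* outflow shifted by
  `round(tau/dt)` steps. Clipping (a dispatch exceeding sender stock,
  floored at the available amount and flagged) therefore propagates
  automatically, and the mass-balance residual of any run is zero up to
  floating-point accumulation. `mass_balance()` checks
  initial + manufacturer dispatches = final + in transit + dispensed.

Remaining discretization error is first order and comes from clamping and
from event days not on the grid; the step-halving test asserts the error
bound shrinks with `dt`. Tie-breaks and degenerate cases: within one step
arrivals are applied before withdrawals (no spurious one-step stockouts at
arrival instants); dispensing is `min(demand, stock)` with the shortfall
logged as unmet demand, which is *lost*, not backlogged (backlogging would
be a straightforward extension); stockout days are counted on the daily
grid at a threshold of 1e-9 packages; Gaussian pulses are truncated to
exactly zero beyond $K B = 6B$ days from the peak (tail mass below
$10^{-15}$ of the size), so a pulse never leaks across unrelated periods;
overlapping pulses add linearly; a per-shipment size override rescales $A$
with $B$ fixed.

## The built-in scenarios

`fixture_scenario()` encodes a representative low-income-country chain:
transport times of 60/15/3 days, a 180-day manufacturer cycle, a 60-day
procurer cycle, 14-day facility deliveries, a high season starting on day
100 and a moderate season on day 250. These structural values, and the
amplitudes, initial stocks and controller settings around them, are fixed
once here:

* **baseline** (open loop): facility deliveries of 40 packages every 14
  days against demand of 4 packages/day (56 per cycle), so stockouts recur
  and lengthen — the failure mode the controller addresses. Upstream sizes
  (240 per 60 days, 720 per 180 days) exactly match throughput. Initial
  stocks 1500/800/60 packages.
* **tracking**: the same chain with the controller on every link
  ($L_H = 10$, $d_W = 2$ following the worked forecasting example's
  pattern).
* **seasonal**: a three-season year (4, 10, 6 packages/day with breaks at
  days 100 and 250, high > moderate > low) under the controller with
  $L_H = 50$. The day-100 step lands inside one forecasting window, so the
  stock dips below $L_H$ exactly once before the next decision corrects
  it.

These scenarios emulate the *structure* of real supply-chain data —
delays, periodic pulses, seasonality, feedback — but none of its noise:
demand is deterministic, transport times never vary, nothing is lost in
transit, and one aggregate compartment stands for each tier. Passing tests
therefore demonstrate correctness of the mechanism, not calibration to any
country's data; fitting to real consumption records is explicitly out of
scope here.

## Problem sizes

Simulations in the tests and the acceptance script run 200–365 day
horizons at `dt = 0.05` (7 300 steps; 0.01 for the discrete-limit
comparison), which resolves every pulse width used while keeping a full
suite run under half a minute.

## Worked example

```{r example}
cfg <- fixture_scenario("tracking")
traj <- simulate_scenario(cfg)
glance(traj)
traj$decisions |> filter(link == "WH") |> head(4)
```

## Known limitations

Single product per scenario (multi-drug studies are independent runs); one
aggregate node per tier (no geography); no stochasticity; no economic
evaluation of interventions; the demand forecast inside the controller is
the constant-rate assumption only — no smoothing or regression forecasts;
unmet demand is lost rather than backlogged.
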