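# Health-system interventions as parameter transforms, and the outcome
# metrics used to compare scenarios.

#' Apply a health-system intervention to a scenario
#'
#' Maps system-wide interventions onto the model parameters and returns a
#' new scenario (the input is never modified):
#' * `"prevention"` — investment in prevention (e.g. immunization) lowers
#'   population demand: the demand scale is multiplied by `factor`.
#' * `"roads"` — better roads shorten transport: `tau` on the chosen links
#'   is multiplied by `factor`, accompanied by a shipment-size increase
#'   (`A` multiplied by `size_factor`) standing in for deliveries now
#'   reaching previously inaccessible facilities.
#' * `"workforce"` — more delivery personnel means more frequent shipments:
#'   `n` is multiplied by `factor` (< 1 shortens the period).
#' * `"vehicles"` — higher-capacity vehicles carry larger shipments: `A` is
#'   multiplied by `factor`.
#'
#' @param cfg An `sc_scenario`.
#' @param kind One of `"prevention"`, `"roads"`, `"workforce"`, `"vehicles"`.
#' @param factor Main transform magnitude (> 0; reductions use factors < 1).
#' @param links Link ids the transform touches (default `"WH"`, the
#'   warehouse-to-facility leg); ignored for `"prevention"`.
#' @param size_factor Shipment-size multiplier accompanying `"roads"`
#'   (default 1.1, an illustrative value).
#' @return A new `sc_scenario`; it must still pass [validate_scenario()],
#'   otherwise an error is raised.
#' @examples
#' base <- fixture_scenario("baseline")
#' less_demand <- apply_intervention(base, "prevention", factor = 0.5)
#' faster <- apply_intervention(base, "workforce", factor = 0.5)
#' @export
apply_intervention <- function(cfg, kind = c("prevention", "roads", "workforce", "vehicles"),
                               factor, links = "WH", size_factor = 1.1) {
  kind <- match.arg(kind)
  stopifnot(factor > 0)
  out <- cfg
  ids <- link_id(out$links$from, out$links$to)
  touch <- ids %in% links
  switch(kind,
    prevention = {
      out$demand$scale <- out$demand$scale * factor
    },
    roads = {
      out$links$tau[touch] <- out$links$tau[touch] * factor
      out$links$A[touch] <- out$links$A[touch] * size_factor
    },
    workforce = {
      out$links$n[touch] <- out$links$n[touch] * factor
    },
    vehicles = {
      out$links$A[touch] <- out$links$A[touch] * factor
    }
  )
  v <- validate_scenario(out)
  if (length(v)) {
    abort(paste0("intervention '", kind, "' breaks scenario invariants:\n",
                 paste("-", v, collapse = "\n")))
  }
  out
}

#' Count stockout days at health facilities
#'
#' Number of whole days in the window whose sampled facility stock is at or
#' below the stockout threshold (1e-9 packages by default), on a daily grid.
#' Trajectories sampled finer than daily are resampled; coarser sampling is
#' an error.
#'
#' @param traj An `sc_trajectory`.
#' @param window Numeric `c(start, end)` in days; default the whole horizon.
#' @param threshold Stock level counted as empty (packages).
#' @return Integer number of stockout days.
#' @export
stockout_days <- function(traj, window = NULL, threshold = .stockout_threshold) {
  daily <- if (abs(traj$interval - 1) < 1e-9) traj else resample_trajectory(traj, 1)
  s <- daily$series
  window <- window %||% c(0, traj$horizon)
  if (window[1] < -1e-9 || window[2] > traj$horizon + 1e-9) {
    abort("window outside the trajectory horizon")
  }
  keep <- s$t >= window[1] - 1e-9 & s$t <= window[2] + 1e-9
  sum(s$Y_H[keep] <= threshold)
}

#' Stockout days per inter-arrival interval
#'
#' Splits the horizon at the facility arrival days and counts stockout days
#' inside each interval — the "stockout period between shipments". Reported
#' per interval with the max and mean available via [scenario_report()].
#'
#' @param traj An `sc_trajectory`.
#' @param threshold Stock level counted as empty (packages).
#' @return Tibble `interval_start, interval_end, stockout_days`.
#' @export
stockout_between_shipments <- function(traj, threshold = .stockout_threshold) {
  arr <- sort(unique(traj$shipments$arrival_day[traj$shipments$link == "WH"]))
  arr <- arr[arr <= traj$horizon]
  bounds <- unique(c(0, arr, traj$horizon))
  purrr::map_dfr(seq_len(length(bounds) - 1L), function(i) {
    tibble(
      interval_start = bounds[i],
      interval_end = bounds[i + 1],
      stockout_days = stockout_days(traj, c(bounds[i], bounds[i + 1]),
                                    threshold = threshold)
    )
  })
}

#' Compare labelled scenario runs
#'
#' One row per scenario: stockout days, total unmet demand, min/mean/max
#' facility stock, total shipped per link, and the mean total stock held
#' across P, W, H (a proxy for expiry risk — stock sitting in the system).
#'
#' @param ... Named `sc_trajectory` objects, or a single named list of them.
#' @return A tibble with one row per scenario.
#' @examples
#' base <- simulate_scenario(fixture_scenario("baseline"))
#' scenario_report(baseline = base)
#' @export
scenario_report <- function(...) {
  dots <- list(...)
  if (length(dots) == 1 && is.list(dots[[1]]) && !inherits(dots[[1]], "sc_trajectory")) {
    dots <- dots[[1]]
  }
  if (is.null(names(dots)) || any(names(dots) == "")) {
    abort("scenario_report() needs named trajectories")
  }
  horizons <- vapply(dots, function(x) x$horizon, numeric(1))
  if (length(unique(horizons)) != 1) {
    abort(sprintf("mismatched horizons: %s", paste(unique(horizons), collapse = ", ")))
  }
  purrr::imap_dfr(dots, function(traj, nm) {
    s <- traj$series
    tibble(
      scenario = nm,
      stockout_days = stockout_days(traj),
      unmet_total = traj$totals$unmet,
      min_Y_H = min(s$Y_H),
      mean_Y_H = mean(s$Y_H),
      max_Y_H = max(s$Y_H),
      shipped_MP = traj$totals$dispatched[["MP"]],
      shipped_PW = traj$totals$dispatched[["PW"]],
      shipped_WH = traj$totals$dispatched[["WH"]],
      mean_total_stock = mean(s$Y_P + s$Y_W + s$Y_H)
    )
  })
}

#' Export trajectory tables as CSV
#'
#' Writes the sampled series and, when present, the shipment and decision
#' logs next to it (`<stem>.csv`, `<stem>_shipments.csv`,
#' `<stem>_decisions.csv`).
#'
#' @param traj An `sc_trajectory`.
#' @param stem Output path without extension.
#' @return The paths written, invisibly.
#' @export
write_trajectory_csv <- function(traj, stem) {
  paths <- paste0(stem, ".csv")
  utils::write.csv(traj$series, paths, row.names = FALSE)
  if (nrow(traj$shipments)) {
    p <- paste0(stem, "_shipments.csv")
    utils::write.csv(traj$shipments, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(traj$decisions) && nrow(traj$decisions)) {
    p <- paste0(stem, "_decisions.csv")
    utils::write.csv(traj$decisions, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
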