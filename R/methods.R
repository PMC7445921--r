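# broom-style accessors and ggplot2 methods for trajectories.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a trajectory into long format
#'
#' @param x An `sc_trajectory`.
#' @param ... Unused.
#' @return Tibble `t, series, value, type` with one row per sampled value;
#'   `type` distinguishes stocks (packages), flows (packages/day) and demand
#'   rates.
#' @exportS3Method generics::tidy
tidy.sc_trajectory <- function(x, ...) {
  long <- tidyr::pivot_longer(x$series, -"t",
                              names_to = "series", values_to = "value")
  long$type <- dplyr::case_when(
    long$series %in% c("Y_P", "Y_W", "Y_H") ~ "stock",
    long$series %in% c("F_MP", "F_PW", "F_WH") ~ "flow",
    TRUE ~ "demand"
  )
  long
}

#' One-row summary of a trajectory
#'
#' @param x An `sc_trajectory`.
#' @param ... Unused.
#' @return Tibble with horizon, step, stockout days, unmet demand, facility
#'   stock summaries, shipment count and the mass-balance residual.
#' @exportS3Method generics::glance
glance.sc_trajectory <- function(x, ...) {
  s <- x$series
  tibble(
    horizon = x$horizon,
    dt = x$dt,
    closed_loop = x$controller_used,
    stockout_days = stockout_days(x),
    unmet_total = x$totals$unmet,
    min_Y_H = min(s$Y_H),
    mean_Y_H = mean(s$Y_H),
    max_Y_H = max(s$Y_H),
    n_shipments = nrow(x$shipments),
    mass_residual = mass_balance(x)
  )
}

#' Plot a simulated trajectory
#'
#' Stocks and/or flow rates over time, one facet per series, in the layout
#' used to compare the compartments of the chain.
#'
#' @param object An `sc_trajectory`.
#' @param what `"stocks"`, `"flows"` or `"all"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.sc_trajectory <- function(object, what = c("all", "stocks", "flows"), ...) {
  what <- match.arg(what)
  long <- tidy(object)
  keep <- switch(what,
    stocks = long$type == "stock",
    flows = long$type == "flow",
    all = rep(TRUE, nrow(long))
  )
  long <- long[keep, , drop = FALSE]
  long$series <- factor(long$series, levels = c(
    "F_MP", "Y_P", "F_PW", "Y_W", "F_WH", "Y_H", "D", "unmet"
  ))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue4") +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "time (days)", y = "packages or packages/day") +
    ggplot2::theme_minimal()
}

#' Compare facility stock across scenarios
#'
#' @param ... Named `sc_trajectory` objects, or one named list of them.
#' @param desired Optional desired level `L_H` drawn as a reference line.
#' @return A ggplot object of `Y_H(t)` per scenario, one facet each.
#' @export
plot_facility_stock <- function(..., desired = NULL) {
  dots <- list(...)
  if (length(dots) == 1 && is.list(dots[[1]]) && !inherits(dots[[1]], "sc_trajectory")) {
    dots <- dots[[1]]
  }
  df <- purrr::imap_dfr(dots, function(traj, nm) {
    tibble(scenario = nm, t = traj$series$t, Y_H = traj$series$Y_H)
  })
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$Y_H)) +
    ggplot2::geom_line(colour = "steelblue4") +
    ggplot2::facet_wrap(~scenario) +
    ggplot2::labs(x = "time (days)", y = "facility stock (pkgs)") +
    ggplot2::theme_minimal()
  if (!is.null(desired)) {
    p <- p + ggplot2::geom_hline(yintercept = desired, colour = "firebrick",
                                 linetype = "dashed")
  }
  p
}
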