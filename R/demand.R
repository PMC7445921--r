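# Demand models: the dispensing rate D(t) (packages/day) withdrawn from the
# health-facility stock. Demand is drained continuously as a rate, not as
# discrete patient arrivals. The `scale` multiplier is the hook used by the
# prevention intervention.

#' Demand models
#'
#' Three forms of the facility demand rate `D(t)`:
#' * `demand_constant(rate)` — a fixed rate for all t.
#' * `demand_seasonal(segments)` — piecewise-constant seasons; `segments` is a
#'   data frame with columns `start`, `end`, `rate`, contiguous and
#'   non-overlapping. The rate is right-continuous at season starts: at the
#'   first day of the high season the high rate already applies.
#' * `demand_tabulated(table)` — sampled `(day, rate)` pairs, linearly
#'   interpolated.
#'
#' @param rate Constant dispensing rate in packages/day (>= 0).
#' @param segments Data frame `start, end, rate` (days, days, packages/day).
#' @param table Data frame whose first two columns are day and rate
#'   (packages/day), e.g. as read from a two-column CSV.
#' @param scale Dimensionless multiplier applied to the whole curve
#'   (default 1); interventions that lower population demand shrink it.
#' @return An object of class `sc_demand`.
#' @examples
#' demand_rate(demand_constant(4), 10)
#' seas <- demand_seasonal(data.frame(
#'   start = c(0, 100, 250), end = c(100, 250, 365), rate = c(4, 10, 6)
#' ))
#' demand_rate(seas, c(99, 100, 250))
#' @export
demand_constant <- function(rate, scale = 1) {
  stopifnot(rate >= 0, scale >= 0)
  structure(
    list(form = "constant", rate = as.numeric(rate), scale = as.numeric(scale)),
    class = "sc_demand"
  )
}

#' @rdname demand_constant
#' @export
demand_seasonal <- function(segments, scale = 1) {
  seg <- as_tibble(segments)[, c("start", "end", "rate")]
  seg <- dplyr::arrange(seg, .data$start)
  structure(
    list(form = "piecewise_seasonal", segments = seg, scale = as.numeric(scale)),
    class = "sc_demand"
  )
}

#' @rdname demand_constant
#' @export
demand_tabulated <- function(table, scale = 1) {
  tab <- as.data.frame(table)[, 1:2]
  names(tab) <- c("day", "rate")
  tab <- tab[order(tab$day), ]
  structure(
    list(form = "tabulated", table = as_tibble(tab), scale = as.numeric(scale)),
    class = "sc_demand"
  )
}

# Domain over which the model is defined: [lo, hi] (hi may be Inf).
demand_domain <- function(model) {
  switch(model$form,
    constant = c(0, Inf),
    piecewise_seasonal = c(min(model$segments$start), max(model$segments$end)),
    tabulated = range(model$table$day)
  )
}

check_demand_window <- function(model, lo, hi, what = "t") {
  dom <- demand_domain(model)
  if (lo < dom[1] - 1e-9 || hi > dom[2] + 1e-9) {
    abort(sprintf(
      "%s in [%g, %g] is outside the demand model's domain [%g, %g]",
      what, lo, hi, dom[1], dom[2]
    ))
  }
  invisible(NULL)
}

validate_demand <- function(model, horizon) {
  v <- character()
  if (!inherits(model, "sc_demand")) {
    return("demand: not an sc_demand model")
  }
  if (model$scale < 0) v <- c(v, sprintf("demand scale = %g violates scale >= 0", model$scale))
  if (model$form == "constant") {
    if (model$rate < 0) v <- c(v, sprintf("demand rate = %g violates rate >= 0", model$rate))
  } else if (model$form == "piecewise_seasonal") {
    seg <- model$segments
    if (any(seg$rate < 0)) v <- c(v, "demand segments: negative rate")
    if (nrow(seg) > 1 && any(abs(seg$start[-1] - seg$end[-nrow(seg)]) > 1e-9)) {
      v <- c(v, "demand segments: not contiguous/non-overlapping")
    }
    if (seg$start[1] > 1e-9 || seg$end[nrow(seg)] < horizon - 1e-9) {
      v <- c(v, sprintf("demand segments do not cover [0, %g]", horizon))
    }
  } else if (model$form == "tabulated") {
    if (any(model$table$rate < 0)) v <- c(v, "demand table: negative rate")
    dom <- demand_domain(model)
    if (dom[1] > 1e-9 || dom[2] < horizon - 1e-9) {
      v <- c(v, sprintf("demand table does not cover [0, %g]", horizon))
    }
  }
  v
}

#' Evaluate the demand rate D(t)
#'
#' @param model An `sc_demand`.
#' @param t Time(s) in days; must lie inside the model's domain (the covered
#'   horizon for seasonal/tabulated forms), otherwise an error names the bound.
#' @return Dispensing rate(s) in packages/day, `scale` included. The seasonal
#'   form is right-continuous at segment boundaries.
#' @export
demand_rate <- function(model, t) {
  check_demand_window(model, min(t), max(t))
  r <- switch(model$form,
    constant = rep(model$rate, length(t)),
    piecewise_seasonal = {
      seg <- model$segments
      idx <- findInterval(t, seg$start)
      idx[idx < 1] <- 1L
      idx[idx > nrow(seg)] <- nrow(seg)
      seg$rate[idx]
    },
    tabulated = stats::approx(model$table$day, model$table$rate, xout = t,
                              rule = 2)$y
  )
  model$scale * r
}

# Cumulative demand C(t) = integral of D over [0, t] (or domain start),
# vectorized; exact for constant/seasonal, trapezoid-exact for tabulated
# (the interpolant is piecewise linear, so the trapezoid rule IS its integral).
demand_cumulative <- function(model, t) {
  out <- switch(model$form,
    constant = model$rate * t,
    piecewise_seasonal = {
      seg <- model$segments
      acc <- numeric(length(t))
      for (i in seq_len(nrow(seg))) {
        acc <- acc + seg$rate[i] * pmax(0, pmin(t, seg$end[i]) - seg$start[i])
      }
      acc
    },
    tabulated = {
      tab <- model$table
      kn <- tab$day
      rt <- tab$rate
      # cumulative trapezoid at the knots
      ck <- c(0, cumsum(diff(kn) * (rt[-1] + rt[-length(rt)]) / 2))
      i <- findInterval(t, kn, rightmost.closed = TRUE)
      i[i < 1] <- 1L
      i[i >= length(kn)] <- length(kn) - 1L
      frac <- t - kn[i]
      slope <- (rt[i + 1] - rt[i]) / (kn[i + 1] - kn[i])
      ck[i] + frac * rt[i] + slope * frac^2 / 2
    }
  )
  model$scale * out
}

#' Mean demand over a window
#'
#' The window-average rate `(1/length) * integral of D(t) dt` over
#' `[start, start + length]`, computed by exact segment arithmetic for the
#' constant and seasonal forms and by the trapezoid rule for tabulated
#' demand. This is the quantity the steady-state shipment-balance condition
#' compares against the per-day shipment mass.
#'
#' @param model An `sc_demand`.
#' @param start Window start in days.
#' @param length Window length in days (> 0).
#' @return Mean rate in packages/day.
#' @examples
#' mean_demand(demand_constant(4), 3, 14)
#' @export
mean_demand <- function(model, start, length) {
  stopifnot(length > 0)
  check_demand_window(model, start, start + length, what = "window")
  (demand_cumulative(model, start + length) - demand_cumulative(model, start)) / length
}

format_demand <- function(model) {
  switch(model$form,
    constant = sprintf("constant %g pkgs/day (scale %g)", model$rate, model$scale),
    piecewise_seasonal = sprintf("seasonal, %d segments (scale %g)",
                                 nrow(model$segments), model$scale),
    tabulated = sprintf("tabulated, %d points (scale %g)",
                        nrow(model$table), model$scale)
  )
}

#' @export
print.sc_demand <- function(x, ...) {
  cat("<sc_demand>", format_demand(x), "\n")
  invisible(x)
}

demand_to_list <- function(model) {
  out <- list(form = model$form, scale = model$scale)
  if (model$form == "constant") out$rate <- model$rate
  if (model$form == "piecewise_seasonal") {
    out$segments <- purrr::transpose(as.list(model$segments))
  }
  if (model$form == "tabulated") out$table <- purrr::transpose(as.list(model$table))
  out
}

demand_from_list <- function(obj) {
  switch(obj$form,
    constant = demand_constant(obj$rate, scale = obj$scale %||% 1),
    piecewise_seasonal = demand_seasonal(
      dplyr::bind_rows(lapply(obj$segments, as_tibble)),
      scale = obj$scale %||% 1
    ),
    tabulated = demand_tabulated(
      dplyr::bind_rows(lapply(obj$table, as_tibble)),
      scale = obj$scale %||% 1
    ),
    abort(sprintf("unknown demand form '%s'", obj$form))
  )
}
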