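#' @importFrom rlang %||% abort .data
#' @importFrom dplyr filter mutate arrange bind_rows group_by summarise ungroup
#' @importFrom tibble tibble as_tibble
NULL

# Compartment roles: M (manufacturers, unbounded source), P (procurers),
# W (warehouses), H (health facilities), R (recipients, pure sink).
# Stocks are tracked for P, W, H only; links form the chain M->P->W->H.
.compartments <- c("M", "P", "W", "H", "R")
.stocked <- c("P", "W", "H")
.link_ids <- c("MP", "PW", "WH")

#' Define one supply-chain link
#'
#' A link carries shipments from one compartment to the next along the chain
#' manufacturers -> procurers -> warehouses -> health facilities. Each link has
#' a transport time `tau` (days between dispatch and arrival), a shipment
#' periodicity `n` (days between scheduled dispatches), and a Gaussian pulse
#' shape: amplitude `A` (packages/day), width `B` (days; `B = 0` selects
#' instantaneous, discrete shipments) and first peak time `r0` (days).
#'
#' @param from,to Single characters among `"M"`, `"P"`, `"W"`, `"H"`.
#' @param tau Transport time in days (>= 0).
#' @param n Shipment periodicity in days (> 0).
#' @param A Pulse amplitude in packages/day (>= 0; 0 means no scheduled flow).
#' @param B Pulse width parameter in days (>= 0; 0 = discrete limit).
#' @param r0 Time of the first pulse peak in days.
#' @return A one-row tibble with columns `from, to, tau, n, A, B, r0`;
#'   bind rows of these to build the `links` table of [scenario_config()].
#' @examples
#' link_params("W", "H", tau = 3, n = 14, A = 22.6, B = 1, r0 = 8)
#' @export
link_params <- function(from, to, tau, n, A = 0, B = 0, r0 = 0) {
  tibble(
    from = as.character(from), to = as.character(to),
    tau = as.numeric(tau), n = as.numeric(n),
    A = as.numeric(A), B = as.numeric(B), r0 = as.numeric(r0)
  )
}

#' Define the forecasting controller settings for one link
#'
#' The digital-tracking controller sizes each scheduled shipment on a link so
#' that the receiving compartment's stock is pushed back up to its desired
#' level `L`. The size is decided `d` days before the scheduled dispatch.
#'
#' @param from,to The governed link, as in [link_params()].
#' @param L Desired stock level of the *receiving* compartment, in packages.
#' @param d Decision lead time in days (`0 <= d <= n` of the governed link).
#' @param enabled Logical; disabled rows are kept but ignored by the engine.
#' @return One-row tibble with columns `from, to, L, d, enabled`.
#' @examples
#' controller_params("W", "H", L = 50, d = 2)
#' @export
controller_params <- function(from, to, L, d, enabled = TRUE) {
  tibble(
    from = as.character(from), to = as.character(to),
    L = as.numeric(L), d = as.numeric(d), enabled = isTRUE(enabled)
  )
}

#' Assemble a simulation scenario
#'
#' Collects everything one run needs: the link table, a demand model for the
#' facility tier, initial stocks, the horizon and the integration step. Units
#' are fixed globally: time in days, stock in packages, flows in packages/day.
#'
#' @param links Tibble of link rows from [link_params()] (any subset of
#'   M->P, P->W, W->H; a missing link simply carries no flow).
#' @param demand A demand model from [demand_constant()], [demand_seasonal()]
#'   or [demand_tabulated()].
#' @param initial_stocks Named numeric vector with entries `P`, `W`, `H`
#'   (packages). Missing names default to 0.
#' @param horizon Simulation length in days (> 0). Time origin t = 0 is the
#'   simulation start; all `r0`, dispatch and decision days are absolute days.
#' @param dt Integration step in days (default 0.05).
#' @param sample_every Output sampling interval in days (>= dt; default 1).
#' @param controller Optional tibble of [controller_params()] rows, or `NULL`
#'   for a purely open-loop scenario.
#' @param truncation_k Gaussian pulses are truncated to exactly zero beyond
#'   `truncation_k * B` days from their peak (default 6; tail mass < 1e-15 of
#'   the shipment size, so the closed-form size A*B*sqrt(pi) is exact to
#'   tolerance).
#' @return An object of class `sc_scenario`.
#' @examples
#' cfg <- scenario_config(
#'   links = link_params("W", "H", tau = 3, n = 14, A = 22.6, B = 1, r0 = 8),
#'   demand = demand_constant(4),
#'   initial_stocks = c(W = 500, H = 60),
#'   horizon = 120
#' )
#' validate_scenario(cfg)
#' @export
scenario_config <- function(links, demand, initial_stocks, horizon,
                            dt = 0.05, sample_every = 1, controller = NULL,
                            truncation_k = 6) {
  stocks <- c(P = 0, W = 0, H = 0)
  if (length(initial_stocks)) {
    stocks[names(initial_stocks)] <- as.numeric(initial_stocks)
  }
  cfg <- structure(
    list(
      links = as_tibble(links),
      demand = demand,
      initial_stocks = stocks[.stocked],
      horizon = as.numeric(horizon),
      dt = as.numeric(dt),
      sample_every = as.numeric(sample_every),
      controller = if (is.null(controller)) NULL else as_tibble(controller),
      truncation_k = as.numeric(truncation_k)
    ),
    class = "sc_scenario"
  )
  cfg
}

link_id <- function(from, to) paste0(from, to)

# Fetch a link row by id ("MP","PW","WH"); NULL when absent.
get_link <- function(cfg, id) {
  ln <- cfg$links[link_id(cfg$links$from, cfg$links$to) == id, , drop = FALSE]
  if (nrow(ln) == 0) NULL else ln[1, , drop = FALSE]
}

#' Validate a scenario against the model invariants
#'
#' Checks every structural rule the simulator relies on: links lie on the
#' M->P->W->H chain and are unique; `tau >= 0`, `n > 0`, `A >= 0`, `B >= 0`;
#' stocks and horizon are admissible; `0 < dt <= sample_every`; controller
#' rows reference existing links with `L >= 0` and `0 <= d <= n`; the demand
#' model is non-negative and covers the horizon.
#'
#' @param cfg An `sc_scenario`.
#' @return Character vector of violation descriptions; `character(0)` when the
#'   scenario is well formed. Violations are returned, never raised.
#' @export
validate_scenario <- function(cfg) {
  v <- character()
  say <- function(...) v <<- c(v, sprintf(...))

  ln <- cfg$links
  ids <- link_id(ln$from, ln$to)
  bad <- !ids %in% .link_ids
  if (any(bad)) say("links: %s not on the chain M->P->W->H", paste(ids[bad], collapse = ", "))
  if (anyDuplicated(ids)) say("links: duplicated link %s", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  for (i in seq_len(nrow(ln))) {
    id <- ids[i]
    if (ln$tau[i] < 0) say("tau_%s = %g violates tau >= 0", id, ln$tau[i])
    if (!(ln$n[i] > 0)) say("n_%s = %g violates n > 0", id, ln$n[i])
    if (ln$A[i] < 0) say("A_%s = %g violates A >= 0", id, ln$A[i])
    if (ln$B[i] < 0) say("B_%s = %g violates B >= 0", id, ln$B[i])
  }

  if (!(cfg$horizon > 0)) say("horizon = %g violates horizon > 0", cfg$horizon)
  if (!(cfg$dt > 0)) say("dt = %g violates dt > 0", cfg$dt)
  if (cfg$dt > cfg$sample_every + 1e-12) {
    say("sample_every = %g violates dt <= sample_every", cfg$sample_every)
  }
  neg <- cfg$initial_stocks < 0
  if (any(neg)) {
    say("initial_stocks[%s] negative", paste(names(cfg$initial_stocks)[neg], collapse = ","))
  }

  if (!is.null(cfg$controller)) {
    ct <- cfg$controller
    for (i in seq_len(nrow(ct))) {
      id <- link_id(ct$from[i], ct$to[i])
      lk <- get_link(cfg, id)
      if (is.null(lk)) {
        say("controller on %s: link not present in scenario", id)
        next
      }
      if (ct$L[i] < 0) say("L_%s = %g violates L >= 0", ct$to[i], ct$L[i])
      if (ct$d[i] < 0) say("d_%s = %g violates d >= 0", ct$from[i], ct$d[i])
      if (ct$d[i] > lk$n) {
        say("d_%s = %g exceeds periodicity n_%s = %g", ct$from[i], ct$d[i], id, lk$n)
      }
    }
  }

  v <- c(v, validate_demand(cfg$demand, cfg$horizon))
  v
}

#' @export
print.sc_scenario <- function(x, ...) {
  cat("<sc_scenario> horizon", x$horizon, "days, dt", x$dt, "day\n")
  cat("initial stocks (pkgs):",
      paste(names(x$initial_stocks), round(x$initial_stocks, 2),
            sep = "=", collapse = " "), "\n")
  cat("demand:", format_demand(x$demand), "\n")
  cat("links:\n")
  print(x$links, ...)
  if (!is.null(x$controller)) {
    cat("controller:\n")
    print(x$controller, ...)
  } else {
    cat("controller: none (open loop)\n")
  }
  invisible(x)
}

#' Write / read a scenario as YAML
#'
#' The document mirrors the scenario fields: `horizon`, `dt`, `sample_every`,
#' `truncation_k`, `initial_stocks` (map P/W/H), `demand` (form-tagged map),
#' `links` (sequence of maps `from,to,tau,n,A,B,r0`) and optionally
#' `controller` (sequence of maps `from,to,L,d,enabled`). Reals are written
#' with 15 significant digits so a round trip reproduces integers bit-exactly
#' and reals to better than 1e-12 relative.
#'
#' @param cfg An `sc_scenario`.
#' @param path File path.
#' @return `write_scenario()` returns `cfg` invisibly; `read_scenario()`
#'   returns the reconstructed `sc_scenario`.
#' @export
write_scenario <- function(cfg, path) {
  obj <- list(
    horizon = cfg$horizon,
    dt = cfg$dt,
    sample_every = cfg$sample_every,
    truncation_k = cfg$truncation_k,
    initial_stocks = as.list(cfg$initial_stocks),
    demand = demand_to_list(cfg$demand),
    links = purrr::transpose(as.list(cfg$links))
  )
  if (!is.null(cfg$controller)) {
    obj$controller <- purrr::transpose(as.list(cfg$controller))
  }
  yaml::write_yaml(obj, path, precision = 15)
  invisible(cfg)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  obj <- yaml::read_yaml(path)
  links <- dplyr::bind_rows(lapply(obj$links, as_tibble))
  controller <- if (!is.null(obj$controller)) {
    dplyr::bind_rows(lapply(obj$controller, as_tibble))
  }
  scenario_config(
    links = links,
    demand = demand_from_list(obj$demand),
    initial_stocks = unlist(obj$initial_stocks),
    horizon = obj$horizon,
    dt = obj$dt,
    sample_every = obj$sample_every,
    controller = controller,
    truncation_k = obj$truncation_k %||% 6
  )
}
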