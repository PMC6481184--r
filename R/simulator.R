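# Fixed-step explicit Euler integration of the cell ion contents, with the
# membrane potential re-solved from electroneutrality at every step and the
# volume from osmotic balance. Time unit: minutes.

#' Pump rate coefficient under linear decay
#'
#' `beta(t) = max(0, beta0 - kb * t)`: the pump rate coefficient declines
#' linearly with time and is clamped at zero. Vectorized over `t`.
#'
#' @param beta0 Pump rate coefficient at t = 0 (min^-1).
#' @param kb Decay coefficient (beta units per minute).
#' @param t Time (min).
#' @return beta at time t (min^-1).
#' @examples
#' beta_at(0.029, 0.000068, 240) # 0.01268, prints as 0.013
#' @export
beta_at <- function(beta0, kb, t) {
  stopifnot(beta0 >= 0, kb >= 0, all(t >= 0))
  pmax(0, beta0 - kb * t)
}

# per-ml net flux sums entering the three content rate equations
rate_fluxes <- function(u, na, k, cl, p, medium) {
  g <- 1 - exp(u)
  if (abs(u) < .u_eps) {
    ch_na <- p$pna * (medium$na0 - na)
    ch_k <- p$pk * (medium$k0 - k)
    ch_cl <- p$pcl * (medium$cl0 - cl)
  } else {
    ch_na <- p$pna * u * (na * exp(u) - medium$na0) / g
    ch_k <- p$pk * u * (k * exp(u) - medium$k0) / g
    ch_cl <- p$pcl * u * (cl - medium$cl0 * exp(u)) / g
  }
  j_nc <- p$inc * (medium$na0 * medium$cl0 - na * cl)
  j_kc <- p$ikc * (medium$k0 * medium$cl0 - k * cl)
  j_nkcc <- p$inkcc * (medium$na0 * medium$k0 * medium$cl0^2 - na * k * cl^2)
  c(na = ch_na - p$beta * na + j_nc + j_nkcc,
    k = ch_k + p$beta * na / p$gamma + j_kc + j_nkcc,
    cl = ch_cl + j_nc + j_kc + 2 * j_nkcc)
}

#' One explicit Euler step of the flux-balance equations
#'
#' Solves the membrane potential at the current state, evaluates the three
#' content rate equations (`dNa_i/dt = V * {channel - pump + NC + NKCC}`
#' and its K and Cl analogues, Cl receiving `2 * J_NKCC`), advances the
#' contents by `dt`, recomputes the volume from osmotic balance and the
#' concentrations from the contents, and re-solves the potential at the new
#' state. `params$beta` is used as given; apply [beta_at()] first when the
#' pump decays.
#'
#' @param state A [cell_state()].
#' @param params A [membrane_params()].
#' @param medium An [external_medium()].
#' @param dt Step size (min, > 0).
#' @return The advanced [cell_state()].
#' @export
step_state <- function(state, params, medium, dt) {
  stopifnot(dt > 0)
  # with no charge-carrying pathway the charge flux vanishes identically
  # and the potential is indeterminate; keep the previous value
  u <- if (!charge_active(params)) {
    if (is.finite(state$u)) state$u else 0
  } else if (is.finite(state$u)) {
    solve_u_warm(state, params, medium, state$u)
  } else solve_potential(state, params, medium)$u
  j <- rate_fluxes(u, state$na, state$k, state$cl, params, medium)
  V <- state$V
  na_i <- state$na * V + V * j[["na"]] * dt
  k_i <- state$k * V + V * j[["k"]] * dt
  cl_i <- state$cl * V + V * j[["cl"]] * dt
  if (min(na_i, k_i, cl_i) <= 0)
    stop("a concentration became non-positive within one step; reduce dt")
  V <- osmotic_volume(na_i, k_i, cl_i, medium)
  state$na <- na_i / V; state$k <- k_i / V; state$cl <- cl_i / V
  state$V <- V
  state$t <- state$t + dt
  if (!charge_active(params)) {
    state$u <- u
    state$U <- 26.7 * u
    return(state)
  }
  solve_potential(state, params, medium)
}

#' Simulation scenario
#'
#' Bundles everything needed for a run: the medium, initial intracellular
#' concentrations, transport parameters, an optional piecewise parameter
#' schedule, and the integration settings.
#'
#' @param medium An [external_medium()].
#' @param params A [membrane_params()].
#' @param na,k,cl Initial intracellular concentrations (mM).
#' @param schedule A [param_schedule()] or `NULL`.
#' @param t_end Simulated time span (min).
#' @param dt Euler step (min).
#' @param hp Number of internal steps between output samples (>= 1).
#' @param label Optional scenario name used in reports.
#' @return An object of class `scenario`.
#' @examples
#' scenario(standard_medium(),
#'          membrane_params(beta = 0.039, pna = 0.00382, pk = 0.022,
#'                          pcl = 0.0091, inc = 3e-5),
#'          na = 33, k = 152, cl = 45, t_end = 240)
#' @export
scenario <- function(medium, params, na, k, cl, schedule = NULL,
                     t_end = 240, dt = 0.01, hp = 100, label = NULL) {
  stopifnot(inherits(medium, "external_medium"),
            inherits(params, "membrane_params"),
            t_end >= 0, dt > 0, hp >= 1)
  if (!is.null(schedule) && !inherits(schedule, "param_schedule"))
    stop("'schedule' must be a param_schedule or NULL")
  structure(list(medium = medium, params = params,
                 na = na, k = k, cl = cl,
                 schedule = schedule, t_end = t_end, dt = dt,
                 hp = as.integer(hp), label = label),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("Scenario%s: t_end %g min, dt %g min, hp %d\n",
              if (is.null(x$label)) "" else paste0(" '", x$label, "'"),
              x$t_end, x$dt, x$hp))
  cat(sprintf("  initial [Na]i %g, [K]i %g, [Cl]i %g mM\n", x$na, x$k, x$cl))
  print(x$medium)
  print(x$params)
  if (!is.null(x$schedule)) print(x$schedule)
  invisible(x)
}

#' Simulate the time course of cell ion and water balance
#'
#' Integrates the content rate equations with fixed-step explicit Euler.
#' At every step the membrane potential is re-solved from zero net charge
#' flux and the volume from osmotic balance; the pump rate coefficient
#' follows [beta_at()] from the time it was last (re)set. Schedule events
#' replace parameters instantaneously at their event time (never earlier).
#' Samples are emitted at t = 0, every `hp`-th internal step, at every
#' event time, and at `t_end`.
#'
#' @param x A [scenario()], or a [cell_state()] (with `params` and `medium`
#'   supplied).
#' @param params,medium,schedule,t_end,dt,hp Override the scenario fields
#'   (required when `x` is a [cell_state()]).
#' @param record_fluxes Attach a [build_flux_table()] per sample.
#' @return A `timecourse` data.frame with columns `t` (min), `U` (mV),
#'   `na`, `k`, `cl` (mM), `V` (ml per mmol A), `mun`, `muk`, `mucl` (mV),
#'   `prna`, `prk`, `prcl` (mM min^-1, finite differences across the last
#'   internal step; zero by convention at t = 0), and `beta` (min^-1).
#'   Attributes: `flux_tables` (list, if recorded), `z`, `medium`,
#'   `final_state` (a [cell_state()]), `final_params`.
#' @examples
#' tc <- simulate_cell(fixture_scenario("table2_balance"), hp = 2400)
#' tail(tc, 1)
#' @export
simulate_cell <- function(x, params = NULL, medium = NULL, schedule = NULL,
                          t_end = NULL, dt = NULL, hp = NULL,
                          record_fluxes = TRUE) {
  if (inherits(x, "scenario")) {
    state <- cell_state(x$na, x$k, x$cl, x$medium)
    params <- params %||% x$params
    medium <- medium %||% x$medium
    schedule <- schedule %||% x$schedule
    t_end <- t_end %||% x$t_end
    dt <- dt %||% x$dt
    hp <- hp %||% x$hp
  } else if (inherits(x, "cell_state")) {
    state <- x
    if (is.null(params) || is.null(medium))
      stop("'params' and 'medium' are required with a cell_state input")
    t_end <- t_end %||% 240
    dt <- dt %||% 0.01
    hp <- hp %||% 100
  } else stop("'x' must be a scenario or a cell_state")
  hp <- max(1L, as.integer(hp))
  stopifnot(t_end >= 0, dt > 0)

  ev_times <- if (is.null(schedule)) numeric() else schedule$times
  ev_ov <- if (is.null(schedule)) list() else schedule$overrides
  ev_next <- 1L

  # beta decays from the time it was last explicitly set
  beta_set <- params$beta
  t_beta_ref <- 0

  n_steps <- max(0L, as.integer(round(t_end / dt)))
  t <- 0
  na <- state$na; k <- state$k; cl <- state$cl
  V <- state$V; z <- state$z
  na_i <- na * V; k_i <- k * V; cl_i <- cl * V

  apply_events <- function(t) {
    while (ev_next <= length(ev_times) && ev_times[ev_next] <= t + 1e-9) {
      ov <- ev_ov[[ev_next]]
      if ("beta" %in% names(ov)) {
        beta_set <<- ov$beta
        t_beta_ref <<- ev_times[ev_next]
      }
      params <<- update_params(params, ov)
      ev_next <<- ev_next + 1L
    }
  }
  apply_events(0)

  sample_steps <- unique(c(0L,
                           if (n_steps >= hp) seq.int(hp, n_steps, by = hp),
                           n_steps))
  if (length(ev_times))
    sample_steps <- sort(unique(c(sample_steps,
                                  as.integer(round(ev_times / dt)))))
  sample_steps <- sample_steps[sample_steps <= n_steps]
  n_out <- length(sample_steps)
  cols <- c("t", "U", "na", "k", "cl", "V", "mun", "muk", "mucl",
            "prna", "prk", "prcl", "beta")
  out <- matrix(NA_real_, n_out, length(cols), dimnames = list(NULL, cols))
  fluxes <- if (record_fluxes) vector("list", n_out) else NULL
  out_i <- 1L

  p0 <- params
  p0$beta <- beta_at(beta_set, p0$kb, 0)
  u <- if (charge_active(p0))
    solve_potential(list(na = na, k = k, cl = cl), p0, medium)$u else 0
  pr <- c(0, 0, 0)

  emit <- function() {
    p_now <- params
    p_now$beta <- beta_at(beta_set, p_now$kb, t - t_beta_ref)
    U <- 26.7 * u
    mu <- c(26.7 * log(na / medium$na0) + U,
            26.7 * log(k / medium$k0) + U,
            26.7 * log(cl / medium$cl0) - U)
    out[out_i, ] <<- c(t, U, na, k, cl, V, mu, pr, p_now$beta)
    if (record_fluxes) {
      st <- structure(list(t = t, na = na, k = k, cl = cl, V = V, z = z,
                           u = u, U = U), class = "cell_state")
      fluxes[[out_i]] <<- build_flux_table(st, p_now, medium)
    }
    out_i <<- out_i + 1L
  }

  step_set <- rep(FALSE, n_steps + 1L)
  step_set[sample_steps + 1L] <- TRUE
  emit()

  if (n_steps > 0) {
    for (i in seq_len(n_steps)) {
      apply_events(t)
      p <- params
      p$beta <- beta_at(beta_set, p$kb, t - t_beta_ref)
      if (charge_active(p))
        u <- solve_u_warm(list(na = na, k = k, cl = cl), p, medium, u)
      j <- rate_fluxes(u, na, k, cl, p, medium)
      na_i <- na_i + V * j[[1L]] * dt
      k_i <- k_i + V * j[[2L]] * dt
      cl_i <- cl_i + V * j[[3L]] * dt
      if (min(na_i, k_i, cl_i) <= 0)
        stop(sprintf(paste0("a concentration became non-positive at ",
                            "t = %.4g min; reduce dt"), t))
      V_new <- (na_i + k_i + cl_i + 1000) / medium_osmolarity(medium)
      na_new <- na_i / V_new; k_new <- k_i / V_new; cl_new <- cl_i / V_new
      pr <- c(na_new - na, k_new - k, cl_new - cl) / dt
      na <- na_new; k <- k_new; cl <- cl_new; V <- V_new
      t <- i * dt
      if (step_set[i + 1L]) {
        apply_events(t)
        p <- params
        p$beta <- beta_at(beta_set, p$kb, t - t_beta_ref)
        if (charge_active(p))
          u <- solve_u_warm(list(na = na, k = k, cl = cl), p, medium, u)
        emit()
      }
    }
  }

  tc <- as.data.frame(out)
  class(tc) <- c("timecourse", "data.frame")
  final_state <- structure(list(t = t, na = na, k = k, cl = cl, V = V,
                                z = z, u = u, U = 26.7 * u),
                           class = "cell_state")
  final_params <- params
  final_params$beta <- beta_at(beta_set, params$kb, t - t_beta_ref)
  attr(tc, "flux_tables") <- fluxes
  attr(tc, "z") <- z
  attr(tc, "medium") <- medium
  attr(tc, "final_state") <- final_state
  attr(tc, "final_params") <- final_params
  tc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.timecourse <- function(x, ...) {
  cat(sprintf("Time course, %d samples over %g min (z = %.4g):\n",
              nrow(x), max(x$t), attr(x, "z")))
  df <- as.data.frame(x)
  if (nrow(df) > 10) {
    print(head(round(df, 4), 5))
    cat(sprintf("  ... %d rows omitted ...\n", nrow(df) - 10L))
    print(tail(round(df, 4), 5))
  } else print(round(df, 4))
  invisible(x)
}

#' Detect arrival at the balanced state
#'
#' The balanced state is reached when influx equals efflux for every
#' permeant ion, i.e. the sampled concentration derivatives all vanish.
#' Reports the first sample at which `max(|prna|, |prk|, |prcl|) < tol`.
#' The t = 0 row carries zero derivatives by convention and is skipped
#' whenever later samples exist.
#'
#' @param timecourse A [simulate_cell()] result.
#' @param tol Threshold on the concentration derivatives (mM min^-1).
#' @return A list with `balanced` (logical) and `time` (min, `NA` if never
#'   balanced).
#' @examples
#' tc <- simulate_cell(fixture_scenario("table2_balance"), hp = 2400)
#' detect_balance(tc)
#' @export
detect_balance <- function(timecourse, tol = 1e-3) {
  stopifnot(nrow(timecourse) >= 1)
  rows <- if (nrow(timecourse) > 1) timecourse[-1, ] else timecourse
  m <- pmax(abs(rows$prna), abs(rows$prk), abs(rows$prcl))
  i <- which(m < tol)
  if (!length(i)) list(balanced = FALSE, time = NA_real_)
  else list(balanced = TRUE, time = rows$t[i[1]])
}

.fixture_names <- c("table2_balance", "fig1_perturbations", "fig2_pumpstop",
                    "fig3_pumpstop_fit", "table4_apoptosis", "table5_shifts")

#' Packaged published scenarios
#'
#' Ready-made [scenario()] objects for the U937-like worked examples:
#' \describe{
#'   \item{table2_balance}{transition to the balanced state of a
#'     high-potential U937-like cell (ends near U -44.7 mV, Na 38, K 147,
#'     Cl 45.1 mM).}
#'   \item{fig1_perturbations}{the same balanced cell, as a base for
#'     single-parameter perturbation scans.}
#'   \item{fig2_pumpstop}{pump turned off (beta 0) at a low-pcl balanced
#'     state; `pcl` selects the chloride-permeability variant (0.1, 0.001
#'     or 0.0001).}
#'   \item{fig3_pumpstop_fit}{pump nearly stopped (beta 0.001) from the
#'     observed pre-block distribution.}
#'   \item{table4_apoptosis}{staurosporine-apoptosis fit: linear pump decay
#'     (kb 6.8e-5) with stepwise channel changes at t = 0 (pk 0.03,
#'     pna 0.003, pcl 0.068) and t = 30 (pk back down to 0.02).}
#'   \item{table5_shifts}{single/combined stepwise channel shifts from the
#'     apoptosis baseline; `variant` one of "pk", "pna", "pk_pna",
#'     "pk_pna_pcl".}
#' }
#'
#' @param name Fixture name; see [list_fixtures()].
#' @param pcl Chloride permeability variant for `fig2_pumpstop`.
#' @param variant Shift variant for `table5_shifts`.
#' @return A [scenario()].
#' @examples
#' fixture_scenario("table4_apoptosis")
#' @export
fixture_scenario <- function(name = .fixture_names, pcl = 1e-4,
                             variant = c("pk_pna_pcl", "pk", "pna", "pk_pna")) {
  name <- match.arg(name)
  med <- standard_medium()
  base_u937 <- membrane_params(beta = 0.039, gamma = 1.5, pna = 0.00382,
                               pk = 0.022, pcl = 0.0091, inc = 3e-5)
  apo_base <- membrane_params(beta = 0.029, gamma = 1.5, pna = 0.0041,
                              pk = 0.0115, pcl = 0.0125, inc = 3e-6)
  switch(name,
    table2_balance = scenario(med, base_u937, na = 33, k = 152, cl = 45,
                              t_end = 240, hp = 240, label = name),
    fig1_perturbations = scenario(med, base_u937, na = 33, k = 152, cl = 45,
                                  t_end = 120, hp = 300, label = name),
    fig2_pumpstop = scenario(med,
                             membrane_params(beta = 0, gamma = 1.5,
                                             pna = 0.006, pk = 0.06,
                                             pcl = pcl),
                             na = 52.6, k = 144.2, cl = 11.9,
                             t_end = 240, hp = 100, label = name),
    fig3_pumpstop_fit = scenario(med,
                                 membrane_params(beta = 0.001, gamma = 1.5,
                                                 pna = 0.00301, pk = 0.023,
                                                 pcl = 0.00405, inc = 3.4e-5),
                                 na = 35, k = 156, cl = 70,
                                 t_end = 240, hp = 100, label = name),
    table4_apoptosis = scenario(med, apo_base, na = 32, k = 117, cl = 40,
      schedule = param_schedule(
        c(0, 30),
        list(list(pk = 0.03, pna = 0.003, pcl = 0.068, kb = 0.000068),
             list(pk = 0.02))),
      t_end = 240, hp = 1000, label = name),
    table5_shifts = {
      variant <- match.arg(variant)
      ov <- switch(variant,
                   pk = list(pk = 0.03),
                   pna = list(pna = 0.003),
                   pk_pna = list(pk = 0.03, pna = 0.003),
                   pk_pna_pcl = list(pk = 0.03, pna = 0.003, pcl = 0.068))
      scenario(med, apo_base, na = 32, k = 117, cl = 40,
               schedule = param_schedule(0, list(ov)),
               t_end = 60, hp = 500,
               label = paste0(name, ":", variant))
    })
}

#' @rdname fixture_scenario
#' @export
list_fixtures <- function() .fixture_names
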