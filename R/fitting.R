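# Parameter identification against observed ion time courses: sum-of-squares
# objective, derivative-free (grid + Nelder-Mead) search, an OSOR
# plausibility filter, sensitivity scans, and a synthetic-observation
# generator for recovery tests.

#' Sum-of-squares misfit between observations and a scenario
#'
#' Simulates the candidate scenario and sums, over the observed time points
#' and the three ions, the squared residuals between observed and simulated
#' concentrations. Simulated values are linearly interpolated in time
#' between samples.
#'
#' @param observed A data.frame with columns `t`, `na`, `k`, `cl`
#'   (min, mM). `NA` concentrations are skipped.
#' @param candidate A [scenario()]; its `t_end` must cover the observed
#'   times.
#' @param timecourse Optionally, an already-computed [simulate_cell()]
#'   result for `candidate` (to avoid re-simulation).
#' @return Total squared misfit (mM^2).
#' @examples
#' scn <- fixture_scenario("table4_apoptosis")
#' obs <- make_synthetic_observations(scn, sample_times = c(30, 120, 240))
#' sse_objective(obs, scn) # 0: data generated from the candidate itself
#' @export
sse_objective <- function(observed, candidate, timecourse = NULL) {
  observed <- validate_observations(observed)
  if (is.null(timecourse))
    timecourse <- simulate_cell(candidate, record_fluxes = FALSE)
  if (max(observed$t) > max(timecourse$t) + 1e-9 || min(observed$t) < 0)
    stop("observed times fall outside the simulated range")
  total <- 0
  for (ion in c("na", "k", "cl")) {
    keep <- is.finite(observed[[ion]])
    if (!any(keep)) next
    sim <- stats::approx(timecourse$t, timecourse[[ion]],
                         xout = observed$t[keep], rule = 2)$y
    total <- total + sum((observed[[ion]][keep] - sim)^2)
  }
  total
}

validate_observations <- function(observed) {
  observed <- as.data.frame(observed)
  need <- c("t", "na", "k", "cl")
  if (!all(need %in% names(observed)))
    stop("observed data must have columns t, na, k, cl")
  if (nrow(observed) == 0) stop("observed data set is empty")
  observed[order(observed$t), need]
}

# apply one free-parameter value to a scenario; names are either plain
# membrane_params fields ("pk") or schedule overrides ("pk@60")
set_free_param <- function(scn, name, value) {
  value <- as.numeric(value)[1] # strip names so they cannot leak into fluxes
  if (grepl("@", name, fixed = TRUE)) {
    parts <- strsplit(name, "@", fixed = TRUE)[[1]]
    field <- parts[1]
    at <- as.numeric(parts[2])
    if (is.null(scn$schedule) || !any(abs(scn$schedule$times - at) < 1e-9))
      stop(sprintf("no schedule event at t = %s for free parameter '%s'",
                   parts[2], name))
    i <- which(abs(scn$schedule$times - at) < 1e-9)[1]
    if (!field %in% .param_names)
      stop("unknown parameter name: ", field)
    scn$schedule$overrides[[i]][[field]] <- value
  } else {
    if (!name %in% .param_names)
      stop("unknown parameter name: ", name)
    scn$params <- update_params(scn$params, stats::setNames(list(value), name))
  }
  scn
}

apply_free_params <- function(scn, free_names, values) {
  for (i in seq_along(free_names))
    scn <- set_free_param(scn, free_names[i], values[i])
  scn
}

#' Fit transport parameters to an observed ion time course
#'
#' Derivative-free minimization of [sse_objective()] over the named free
#' parameters: a coarse grid over the bounds picks a starting point, which
#' a bound-clamped Nelder-Mead simplex then refines. Candidate parameter
#' sets whose simulated OSOR at the final time falls below `osor_min` are
#' rejected (infinite objective), implementing the plausibility filter
#' that discards fits incompatible with the measured pump share of K+
#' influx. No gradient method is used: the misfit surface has poorly
#' conditioned curvature.
#'
#' @param observed Observed data.frame (`t`, `na`, `k`, `cl`).
#' @param candidate A [scenario()] holding everything that is not free.
#' @param free_names Character vector: [membrane_params()] field names
#'   ("pk") or schedule overrides ("pk\@60"; the event must exist).
#' @param lower,upper Numeric bounds, one per free parameter (finite).
#' @param osor_min Minimum acceptable OSOR at the final simulated time;
#'   `0` disables the filter.
#' @param n_grid Grid points per dimension for the initial scan.
#' @param control Passed to [stats::optim()] (Nelder-Mead stage).
#' @return An object of class `ion_fit`: list with `par` (best accepted
#'   values), `sse`, `osor`, `accepted` (FALSE when every candidate failed
#'   the OSOR filter), `scenario` (candidate with fitted values applied),
#'   `free_names`, `n_rejected`, and `grid` (the scanned grid with its
#'   objective values).
#' @examples
#' scn <- fixture_scenario("table5_shifts", variant = "pk")
#' obs <- make_synthetic_observations(scn, sample_times = seq(10, 60, 10))
#' fit_parameters(obs, scn, "pk@0", lower = 0.01, upper = 0.05,
#'                n_grid = 3)
#' @export
fit_parameters <- function(observed, candidate, free_names, lower, upper,
                           osor_min = 0, n_grid = 5, control = list()) {
  observed <- validate_observations(observed)
  stopifnot(length(free_names) >= 1,
            length(lower) == length(free_names),
            length(upper) == length(free_names),
            all(is.finite(lower)), all(is.finite(upper)),
            all(lower <= upper))
  n_rejected <- 0L

  eval_candidate <- function(values) {
    values <- pmin(pmax(values, lower), upper)
    scn <- apply_free_params(candidate, free_names, values)
    tc <- simulate_cell(scn, record_fluxes = FALSE)
    ft <- build_flux_table(attr(tc, "final_state"),
                           attr(tc, "final_params"), scn$medium)
    osor <- tryCatch(compute_osor(ft), error = function(e) NA_real_)
    sse <- sse_objective(observed, scn, timecourse = tc)
    if (osor_min > 0 && (!is.finite(osor) || osor < osor_min)) {
      n_rejected <<- n_rejected + 1L
      return(list(sse = Inf, osor = osor))
    }
    list(sse = sse, osor = osor)
  }

  axes <- lapply(seq_along(lower), function(i) {
    if (lower[i] == upper[i]) lower[i]
    else seq(lower[i], upper[i], length.out = n_grid)
  })
  grid <- as.matrix(expand.grid(axes))
  colnames(grid) <- free_names
  grid_eval <- apply(grid, 1, eval_candidate)
  grid_sse <- vapply(grid_eval, `[[`, numeric(1), "sse")

  if (!any(is.finite(grid_sse))) {
    return(structure(list(par = NULL, sse = Inf, osor = NA_real_,
                          accepted = FALSE, scenario = candidate,
                          free_names = free_names,
                          n_rejected = n_rejected,
                          grid = cbind(as.data.frame(grid), sse = grid_sse)),
                     class = "ion_fit"))
  }
  start <- grid[which.min(grid_sse), , drop = TRUE]

  # rejected candidates get a large finite penalty so the derivative-free
  # optimizers never see Inf
  obj <- function(values) {
    v <- eval_candidate(values)$sse
    if (is.finite(v)) v else 1e12
  }
  best <- if (length(free_names) == 1) {
    o <- stats::optimize(obj, c(lower, upper), tol = 1e-8)
    list(par = o$minimum, value = o$objective)
  } else {
    o <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = utils::modifyList(
                        list(reltol = 1e-10, maxit = 500), control))
    list(par = pmin(pmax(o$par, lower), upper), value = o$value)
  }
  if (best$value > min(grid_sse)) # never return worse than the grid best
    best <- list(par = grid[which.min(grid_sse), , drop = TRUE],
                 value = min(grid_sse))

  final <- eval_candidate(best$par)
  structure(list(par = stats::setNames(as.numeric(best$par), free_names),
                 sse = final$sse, osor = final$osor,
                 accepted = is.finite(final$sse),
                 scenario = apply_free_params(candidate, free_names,
                                              best$par),
                 free_names = free_names, n_rejected = n_rejected,
                 grid = cbind(as.data.frame(grid), sse = grid_sse)),
            class = "ion_fit")
}

#' @export
print.ion_fit <- function(x, ...) {
  if (!x$accepted) {
    cat("Fit rejected: no candidate satisfied the OSOR filter",
        sprintf("(%d rejected)\n", x$n_rejected))
    return(invisible(x))
  }
  cat("Fitted parameters:\n")
  for (nm in names(x$par)) cat(sprintf("  %s = %g\n", nm, x$par[[nm]]))
  cat(sprintf("  SSE %.6g mM^2, OSOR %.4g, %d candidate(s) rejected\n",
              x$sse, x$osor, x$n_rejected))
  invisible(x)
}

#' One-at-a-time sensitivity scan of a scenario parameter
#'
#' Repeats the simulation for each trial value of one parameter, everything
#' else fixed, and tabulates the endpoint state of each run -- the "repeat
#' the calculation for slightly different inputs" style of sensitivity
#' analysis natural to this model.
#'
#' @param scn A [scenario()].
#' @param param_name Free-parameter name, as in [fit_parameters()].
#' @param values Trial values (nonempty).
#' @return An object of class `sensitivity_scan`: list with `endpoints`
#'   (data.frame of `value`, final `U`, `na`, `k`, `cl`, `V`) and
#'   `timecourses` (list of [simulate_cell()] results, one per value).
#' @examples
#' sensitivity_scan(fixture_scenario("fig2_pumpstop", pcl = 1e-4),
#'                  "pcl", c(1e-4, 1e-3))
#' @export
sensitivity_scan <- function(scn, param_name, values) {
  stopifnot(length(values) >= 1)
  runs <- lapply(values, function(v)
    simulate_cell(apply_free_params(scn, param_name, v),
                  record_fluxes = FALSE))
  endpoints <- do.call(rbind, lapply(seq_along(runs), function(i) {
    last <- runs[[i]][nrow(runs[[i]]), ]
    data.frame(value = values[i], U = last$U, na = last$na, k = last$k,
               cl = last$cl, V = last$V)
  }))
  structure(list(param_name = param_name, endpoints = endpoints,
                 timecourses = runs),
            class = "sensitivity_scan")
}

#' @export
print.sensitivity_scan <- function(x, ...) {
  cat(sprintf("Sensitivity scan over '%s' (endpoint state per value):\n",
              x$param_name))
  print(round(x$endpoints, 4))
  invisible(x)
}

#' Synthetic observed ion time course from a scenario
#'
#' Simulates the scenario, samples the three ion concentrations at the
#' requested times, and adds independent Gaussian noise per ion and time
#' point. Deterministic for a fixed seed.
#'
#' @param scn A [scenario()].
#' @param sample_times Observation times (min, within `[0, t_end]`).
#' @param noise_sd Noise standard deviation (mM, >= 0).
#' @param seed Optional integer seed.
#' @return A data.frame with columns `t`, `na`, `k`, `cl`.
#' @examples
#' scn <- fixture_scenario("table4_apoptosis")
#' make_synthetic_observations(scn, c(30, 120, 240), noise_sd = 2, seed = 1)
#' @export
make_synthetic_observations <- function(scn, sample_times, noise_sd = 0,
                                        seed = NULL) {
  stopifnot(noise_sd >= 0, length(sample_times) >= 1,
            all(sample_times >= 0), all(sample_times <= scn$t_end))
  if (!is.null(seed)) set.seed(seed)
  tc <- simulate_cell(scn, record_fluxes = FALSE)
  out <- data.frame(t = sort(sample_times))
  for (ion in c("na", "k", "cl")) {
    sim <- stats::approx(tc$t, tc[[ion]], xout = out$t, rule = 2)$y
    out[[ion]] <- sim + if (noise_sd > 0)
      stats::rnorm(nrow(out), 0, noise_sd) else 0
  }
  out
}
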