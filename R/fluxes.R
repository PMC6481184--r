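# Closed-form flux expressions of the pump-leak model.
# All fluxes are in umol min^-1 (ml cell water)^-1; outward net fluxes are
# negative. u is the dimensionless membrane potential (U = 26.7 u at 37 C)
# and g = 1 - exp(u).

# below this |u| the GHK expressions switch to their analytic u -> 0 limits
.u_eps <- 1e-6

#' Goldman-Hodgkin-Katz net channel flux for a monovalent cation
#'
#' Net electrodiffusive flux `p * u * (ci * exp(u) - co) / g` with
#' `g = 1 - exp(u)`; positive values are inward. At `|u| < 1e-6` the
#' analytic limit `p * (co - ci)` is used to avoid 0/0.
#'
#' @param p Channel permeability coefficient (min^-1).
#' @param u Dimensionless membrane potential.
#' @param ci,co Internal and external concentrations (mM).
#' @return Net flux (umol min^-1 ml^-1).
#' @examples
#' ghk_cation_flux(0.00382, -44.7 / 26.7, 38, 140)
#' @export
ghk_cation_flux <- function(p, u, ci, co) {
  stopifnot(p >= 0, ci >= 0, co >= 0)
  if (abs(u) < .u_eps) return(p * (co - ci))
  p * u * (ci * exp(u) - co) / (1 - exp(u))
}

#' Goldman-Hodgkin-Katz net channel flux for a monovalent anion
#'
#' Net flux `p * u * (ci - co * exp(u)) / g` (the valence -1 GHK form),
#' positive inward; limit `p * (co - ci)` at `|u| < 1e-6`. Zero when
#' `ci = co * exp(u)`, the Nernst equilibrium of an anion.
#'
#' @inheritParams ghk_cation_flux
#' @return Net flux (umol min^-1 ml^-1).
#' @examples
#' ghk_anion_flux(0.0091, -44.7 / 26.7, 45.1, 116)
#' @export
ghk_anion_flux <- function(p, u, ci, co) {
  stopifnot(p >= 0, ci >= 0, co >= 0)
  if (abs(u) < .u_eps) return(p * (co - ci))
  p * u * (ci - co * exp(u)) / (1 - exp(u))
}

#' Unidirectional GHK channel fluxes
#'
#' Splits the net GHK flux into its unidirectional components. For a cation
#' influx is `-p*u*co/g` and efflux `p*u*ci*exp(u)/g`; for an anion influx
#' is `-p*u*co*exp(u)/g` and efflux `p*u*ci/g`. For `u < 0` the influx is
#' >= 0 and the efflux <= 0, and their sum equals the corresponding net
#' flux; the `u -> 0` limits are `p*co` and `-p*ci`.
#'
#' @inheritParams ghk_cation_flux
#' @param valence `+1` for a cation, `-1` for an anion.
#' @return Named numeric vector `c(influx, efflux)`.
#' @examples
#' ghk_unidirectional(0.022, -44.7 / 26.7, 147, 5.8, valence = 1)
#' @export
ghk_unidirectional <- function(p, u, ci, co, valence = 1) {
  stopifnot(p >= 0, ci >= 0, co >= 0, valence %in% c(1, -1))
  if (abs(u) < .u_eps) {
    out <- c(influx = p * co, efflux = -p * ci)
    return(out)
  }
  g <- 1 - exp(u)
  if (valence == 1)
    c(influx = -p * u * co / g, efflux = p * u * ci * exp(u) / g)
  else
    c(influx = -p * u * co * exp(u) / g, efflux = p * u * ci / g)
}

#' Na+/K+ pump fluxes
#'
#' First-order pump kinetics: Na+ efflux `-beta * nai` and the coupled K+
#' influx `beta * nai / gamma`. The pump's net charge flux is therefore
#' `-beta * nai * (1 - 1/gamma)`.
#'
#' @param beta Pump rate coefficient (min^-1).
#' @param nai Intracellular Na+ concentration (mM).
#' @param gamma Na/K flux stoichiometry (> 0).
#' @return Named numeric vector `c(na, k)` of net fluxes
#'   (umol min^-1 ml^-1).
#' @examples
#' pump_fluxes(0.039, 38, 1.5)
#' @export
pump_fluxes <- function(beta, nai, gamma = 1.5) {
  stopifnot(beta >= 0, nai >= 0, gamma > 0)
  c(na = -beta * nai, k = beta * nai / gamma)
}

#' Electroneutral cotransporter fluxes
#'
#' Net fluxes driven by the transmembrane products of substrate
#' concentrations:
#' `J_NC = inc * (na0*cl0 - na*cl)`,
#' `J_KC = ikc * (k0*cl0 - k*cl)`,
#' `J_NKCC = inkcc * (na0*k0*cl0^2 - na*k*cl^2)`,
#' each split into a unidirectional influx (the external product term) and
#' efflux (minus the internal product term). Every cotransporter moves
#' equal charge in and out, so none contributes to the charge-flux balance.
#'
#' @param params A [membrane_params()].
#' @param state A [cell_state()] (fields `na`, `k`, `cl` used).
#' @param medium An [external_medium()].
#' @return A list with elements `nc`, `kc`, `nkcc`, each a named vector
#'   `c(net, influx, efflux)` in umol min^-1 ml^-1. The vectors refer to
#'   one stoichiometric turnover unit: Na and Cl both move at `J_NC`, K and
#'   Cl at `J_KC`, and NKCC moves Na and K at `J_NKCC` and Cl at
#'   `2 * J_NKCC`.
#' @examples
#' med <- standard_medium()
#' cotransport_fluxes(membrane_params(inc = 3e-5),
#'                    cell_state(38, 147, 45.1, med), med)
#' @export
cotransport_fluxes <- function(params, state, medium) {
  one <- function(rate, ext, int) {
    c(net = rate * (ext - int), influx = rate * ext, efflux = -rate * int)
  }
  list(
    nc = one(params$inc, medium$na0 * medium$cl0, state$na * state$cl),
    kc = one(params$ikc, medium$k0 * medium$cl0, state$k * state$cl),
    nkcc = one(params$inkcc,
               medium$na0 * medium$k0 * medium$cl0^2,
               state$na * state$k * state$cl^2)
  )
}

#' Transmembrane electrochemical potential differences
#'
#' The driving forces for passive ion movement (mV):
#' `mun = 26.7*ln(na/na0) + U`, `muk = 26.7*ln(k/k0) + U`,
#' `mucl = 26.7*ln(cl/cl0) - U`. Positive values drive the ion outward
#' through its channel.
#'
#' @param state A [cell_state()] with membrane potential `U` (mV) solved.
#' @param medium An [external_medium()].
#' @return Named numeric vector `c(mun, muk, mucl)` (mV).
#' @export
electrochemical_potentials <- function(state, medium) {
  if (any(c(state$na, state$k, state$cl,
            medium$na0, medium$k0, medium$cl0) <= 0))
    stop("electrochemical potentials require positive concentrations")
  if (!is.finite(state$U))
    stop("membrane potential not solved; run solve_potential() first")
  c(mun = 26.7 * log(state$na / medium$na0) + state$U,
    muk = 26.7 * log(state$k / medium$k0) + state$U,
    mucl = 26.7 * log(state$cl / medium$cl0) - state$U)
}

.pathways <- c("PUMP", "Channel", "NC", "KC", "NKCC")
.ions <- c("Na", "K", "Cl")

#' Per-ion, per-pathway flux decomposition
#'
#' Fills the 3 x 5 (ion x pathway) tables of net, unidirectional influx and
#' unidirectional efflux for the pump, channels and the NC/KC/NKCC
#' cotransporters at a given state. The state's membrane potential must
#' already be solved (see [solve_potential()]). Within each cell of the
#' table, net = influx + efflux by construction.
#'
#' @param state A [cell_state()] with `u` solved.
#' @param params A [membrane_params()]; `params$beta` is used as-is (apply
#'   [beta_at()] beforehand for a decaying pump).
#' @param medium An [external_medium()].
#' @return An object of class `flux_table`: a list of three 3 x 5 matrices
#'   `net`, `influx`, `efflux` (rows Na, K, Cl; columns PUMP, Channel, NC,
#'   KC, NKCC), in umol min^-1 (ml cell water)^-1.
#' @examples
#' med <- standard_medium()
#' par <- membrane_params(beta = 0.039, pna = 0.00382, pk = 0.022,
#'                        pcl = 0.0091, inc = 3e-5)
#' st <- solve_potential(cell_state(38, 147, 45.1, med), par, med)
#' build_flux_table(st, par, med)
#' @export
build_flux_table <- function(state, params, medium) {
  if (!is.finite(state$u))
    stop("membrane potential not solved; run solve_potential() first")
  u <- state$u
  m <- function() matrix(0, 3, 5, dimnames = list(.ions, .pathways))
  net <- m(); influx <- m(); efflux <- m()

  pump <- pump_fluxes(params$beta, state$na, params$gamma)
  net["Na", "PUMP"] <- pump[["na"]]; efflux["Na", "PUMP"] <- pump[["na"]]
  net["K", "PUMP"] <- pump[["k"]]; influx["K", "PUMP"] <- pump[["k"]]

  chan <- list(
    Na = ghk_unidirectional(params$pna, u, state$na, medium$na0, valence = 1),
    K  = ghk_unidirectional(params$pk,  u, state$k,  medium$k0,  valence = 1),
    Cl = ghk_unidirectional(params$pcl, u, state$cl, medium$cl0, valence = -1))
  for (ion in .ions) {
    influx[ion, "Channel"] <- chan[[ion]][["influx"]]
    efflux[ion, "Channel"] <- chan[[ion]][["efflux"]]
    net[ion, "Channel"] <- sum(chan[[ion]])
  }

  ct <- cotransport_fluxes(params, state, medium)
  fill <- function(ion, path, f, mult = 1) {
    net[ion, path] <<- mult * f[["net"]]
    influx[ion, path] <<- mult * f[["influx"]]
    efflux[ion, path] <<- mult * f[["efflux"]]
  }
  fill("Na", "NC", ct$nc); fill("Cl", "NC", ct$nc)
  fill("K", "KC", ct$kc); fill("Cl", "KC", ct$kc)
  fill("Na", "NKCC", ct$nkcc); fill("K", "NKCC", ct$nkcc)
  fill("Cl", "NKCC", ct$nkcc, mult = 2)

  structure(list(net = net, influx = influx, efflux = efflux),
            class = "flux_table")
}

#' @export
print.flux_table <- function(x, digits = 4, ...) {
  cat("Fluxes, umol min^-1 (ml cell water)^-1 (outward negative):\n")
  for (nm in c("net", "influx", "efflux")) {
    cat(sprintf("%s:\n", toupper(nm)))
    print(round(x[[nm]], digits))
  }
  invisible(x)
}

#' Ouabain-sensitive over ouabain-resistant K+(Rb+) influx ratio
#'
#' OSOR is the pump-mediated (ouabain-sensitive) K+ influx divided by the
#' total passive (ouabain-resistant) K+ influx through channels and the KC
#' and NKCC cotransporters. Rb+ is assumed to trace K+, so the tracer
#' concentration scaling cancels in the ratio.
#'
#' @param flux_table A [build_flux_table()] result.
#' @return Dimensionless ratio.
#' @examples
#' med <- standard_medium()
#' par <- membrane_params(beta = 0.039, pna = 0.00382, pk = 0.022,
#'                        pcl = 0.0091, inc = 3e-5)
#' st <- solve_potential(cell_state(38, 147, 45.1, med), par, med)
#' compute_osor(build_flux_table(st, par, med))
#' @export
compute_osor <- function(flux_table) {
  num <- flux_table$influx["K", "PUMP"]
  den <- sum(flux_table$influx["K", c("Channel", "KC", "NKCC")])
  if (den <= 0)
    stop("OSOR undefined: no ouabain-resistant K+ influx pathway is active")
  num / den
}

# total net flux of each ion (sum over pathways); the right-hand sides of
# the content rate equations divided by V
total_net_fluxes <- function(flux_table) rowSums(flux_table$net)
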