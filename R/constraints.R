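# The two mandatory constraints of the model: macroscopic electroneutrality
# of ion transfer (solved for the membrane potential) and osmotic balance
# with the medium (solved for the water volume).

#' Impermeant intracellular osmolytes from the initial ion distribution
#'
#' The lumped membrane-impermeant osmolytes (amount A, mean valence z) are
#' chosen so that the initial state satisfies both constraints exactly:
#' osmotic balance gives `A/V = kv*(na0+k0+cl0+B0) - (na+k+cl)` (mM) and
#' electroneutrality gives `z = (cl - na - k) / (A/V)`. A and z are then
#' held constant for the whole simulation; with A normalized to 1 mmol the
#' initial water volume is `V = 1000 / (A/V)` ml.
#'
#' @param na,k,cl Initial intracellular concentrations (mM).
#' @param medium An [external_medium()].
#' @return A list with `a_per_v` (mM), `z` (dimensionless) and `v`
#'   (ml per mmol A).
#' @examples
#' derive_impermeant(33, 152, 45, standard_medium()) # A/V 80 mM, z -1.75
#' @export
derive_impermeant <- function(na, k, cl, medium) {
  a_per_v <- medium_osmolarity(medium) - (na + k + cl)
  if (a_per_v <= 0)
    stop("invalid configuration: internal osmolytes reach or exceed ",
         "external osmolarity, so A/V <= 0")
  z <- (cl - na - k) / a_per_v
  list(a_per_v = a_per_v, z = z, v = 1000 / a_per_v)
}

# TRUE when some charge-carrying pathway (channel or pump) is active, so
# the zero-charge-flux equation determines the potential
charge_active <- function(params) {
  params$pna + params$pk + params$pcl > 0 || params$beta > 0
}

# net charge flux carried across the membrane at potential u:
# channel Na + channel K - channel Cl plus the pump's unbalanced charge.
# Cotransporters are electroneutral and excluded.
charge_flux <- function(u, state, params, medium) {
  ghk_cation_flux(params$pna, u, state$na, medium$na0) +
    ghk_cation_flux(params$pk, u, state$k, medium$k0) -
    ghk_anion_flux(params$pcl, u, state$cl, medium$cl0) -
    params$beta * state$na * (1 - 1 / params$gamma)
}

#' Membrane potential from zero net charge flux
#'
#' Solves `Phi(u) = 0` where `Phi` is the total charge flux through the
#' charge-carrying pathways (channels and pump; cotransporters are
#' electroneutral), treating the potential as instantaneous (the
#' zero-capacitance formulation of the pump-leak lineage). The root is
#' located by a sign-change scan over `bracket` followed by bisection to
#' `|delta u| < tol`.
#'
#' @param state A [cell_state()].
#' @param params A [membrane_params()]; `beta` is used as-is.
#' @param medium An [external_medium()].
#' @param bracket Search interval for the dimensionless potential u.
#' @param tol Bisection half-interval tolerance on u.
#' @return The state with `u` (dimensionless) and `U = 26.7 * u` (mV) set.
#' @examples
#' med <- standard_medium()
#' par <- membrane_params(beta = 0.029, pna = 0.0041, pk = 0.0115,
#'                        pcl = 0.0125, inc = 3e-6)
#' solve_potential(cell_state(32, 117, 40, med), par, med)$U  # ~ -29.9 mV
#' @export
solve_potential <- function(state, params, medium,
                            bracket = c(-8, 2), tol = 1e-10) {
  if (params$pna + params$pk + params$pcl <= 0 && params$beta <= 0)
    stop("no charge-carrying pathway is active; potential is undefined")
  f <- function(u) charge_flux(u, state, params, medium)
  grid <- seq(bracket[1], bracket[2], length.out = 257)
  fv <- vapply(grid, f, numeric(1))
  idx <- which(fv[-length(fv)] * fv[-1] <= 0 &
                 is.finite(fv[-length(fv)]) & is.finite(fv[-1]))
  if (!length(idx)) {
    stop(sprintf(paste0("no sign change of the charge flux in [%g, %g] ",
                        "(Phi endpoints %.6g, %.6g)"),
                 bracket[1], bracket[2], fv[1], fv[length(fv)]))
  }
  lo <- grid[idx[1]]; hi <- grid[idx[1] + 1]
  flo <- fv[idx[1]]
  while ((hi - lo) / 2 > tol) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (flo * fm <= 0) hi <- mid else { lo <- mid; flo <- fm }
  }
  u <- (lo + hi) / 2
  state$u <- u
  state$U <- 26.7 * u
  state
}

# fast warm-started root for the integration loop: Brent on a local bracket
# around the previous u, falling back to the documented full scan.
solve_u_warm <- function(state, params, medium, u_prev) {
  f <- function(u) charge_flux(u, state, params, medium)
  lo <- u_prev - 0.25; hi <- u_prev + 0.25
  flo <- f(lo); fhi <- f(hi)
  if (is.finite(flo) && is.finite(fhi) && flo * fhi <= 0)
    return(stats::uniroot(f, c(lo, hi), f.lower = flo, f.upper = fhi,
                          tol = 1e-12)$root)
  solve_potential(state, params, medium)$u
}

#' Cell water volume from osmotic balance
#'
#' `V = (Na_i + K_i + Cl_i + A) / (kv * (na0 + k0 + cl0 + B0))`: the volume
#' a distensible cell takes so that total internal osmolyte concentration
#' equals the effective external osmolarity.
#'
#' @param na_i,k_i,cl_i Intracellular ion contents (umol per unit A).
#' @param medium An [external_medium()].
#' @param a Impermeant osmolyte amount (mmol; default the normalized 1).
#' @return Water volume (ml per mmol A).
#' @examples
#' osmotic_volume(38 * 12.51, 147 * 12.51, 45.1 * 12.51, standard_medium())
#' @export
osmotic_volume <- function(na_i, k_i, cl_i, medium, a = 1) {
  tot <- na_i + k_i + cl_i + 1000 * a
  if (tot <= 0) stop("total internal osmolyte content must be > 0")
  tot / medium_osmolarity(medium)
}

#' Constraint residuals of a state
#'
#' Diagnostic check of the two constraints at a state: the
#' electroneutrality residual `na + k - cl + z * (A/V)` and the
#' osmotic-balance residual `na + k + cl + A/V - kv * sum(external)`, both
#' in mM.
#'
#' @param state A [cell_state()].
#' @param medium An [external_medium()].
#' @return Named numeric vector `c(electroneutrality, osmotic)` (mM).
#' @export
constraint_residuals <- function(state, medium) {
  a_per_v <- 1000 / state$V
  c(electroneutrality = state$na + state$k - state$cl + state$z * a_per_v,
    osmotic = state$na + state$k + state$cl + a_per_v -
      medium_osmolarity(medium))
}
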