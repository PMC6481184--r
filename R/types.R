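#' External medium composition
#'
#' Fixed bath concentrations of the three permeant ions plus an impermeant
#' non-electrolyte (e.g. mannitol), and an osmolarity scaler `kv` used to
#' represent anisosmotic media ("new" over "old" osmolarity ratio).
#'
#' @param na0,k0,cl0 External Na+, K+, Cl- concentrations (mM).
#' @param b0 External impermeant non-electrolyte concentration (mM).
#' @param kv Dimensionless ratio of new to old media osmolarity.
#' @return An object of class `external_medium`.
#' @examples
#' standard_medium()
#' external_medium(140, 5.8, 116, b0 = 48.2)
#' @export
external_medium <- function(na0, k0, cl0, b0 = 0, kv = 1) {
  conc <- c(na0 = na0, k0 = k0, cl0 = cl0, b0 = b0)
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("external concentrations must be finite and >= 0")
  if (!is.finite(kv) || kv <= 0)
    stop("'kv' must be > 0")
  m <- list(na0 = na0, k0 = k0, cl0 = cl0, b0 = b0, kv = kv)
  if (medium_osmolarity(m) <= 0)
    stop("total external osmolarity must be > 0")
  structure(m, class = "external_medium")
}

#' @rdname external_medium
#' @details `standard_medium()` is the RPMI-like medium used throughout the
#'   worked examples: 140 Na, 5.8 K, 116 Cl, 48.2 mM impermeant
#'   non-electrolyte, 310 mOsm total.
#' @export
standard_medium <- function(kv = 1) external_medium(140, 5.8, 116, b0 = 48.2, kv = kv)

#' Total effective external osmolarity
#'
#' `kv * (na0 + k0 + cl0 + b0)` in mM.
#'
#' @param medium An [external_medium()].
#' @return Osmolarity (mM).
#' @export
medium_osmolarity <- function(medium) {
  medium$kv * (medium$na0 + medium$k0 + medium$cl0 + medium$b0)
}

#' @export
print.external_medium <- function(x, ...) {
  cat("External medium (mM): Na", x$na0, " K", x$k0, " Cl", x$cl0,
      " B0", x$b0, "\n  kv =", x$kv,
      " total osmolarity =", medium_osmolarity(x), "mM\n")
  invisible(x)
}

.param_names <- c("beta", "gamma", "pna", "pk", "pcl",
                  "inc", "ikc", "inkcc", "kb")

#' Membrane transport parameters
#'
#' The full set of rate coefficients of the pump-leak model: pump rate
#' coefficient `beta` (min^-1) with Na/K flux stoichiometry `gamma`
#' (3:2 -> 1.5) and linear decay coefficient `kb` (beta units per minute,
#' so that beta(t) = beta - kb * t, clamped at zero); integral channel
#' permeability coefficients `pna`, `pk`, `pcl` (min^-1); and rate
#' coefficients of the electroneutral cotransporters, `inc` and `ikc`
#' (ml umol^-1 min^-1) and `inkcc` (ml^3 umol^-3 min^-1).
#'
#' @param beta Pump rate coefficient at t = 0 (min^-1).
#' @param gamma Pump Na/K flux stoichiometry (dimensionless, > 0).
#' @param pna,pk,pcl Channel permeability coefficients (min^-1).
#' @param inc,ikc NC and KC cotransport rate coefficients (ml umol^-1 min^-1).
#' @param inkcc NKCC cotransport rate coefficient (ml^3 umol^-3 min^-1).
#' @param kb Linear pump-decay coefficient (beta units min^-1).
#' @return An object of class `membrane_params`.
#' @examples
#' membrane_params(beta = 0.039, pna = 0.00382, pk = 0.022, pcl = 0.0091,
#'                 inc = 3e-5)
#' @export
membrane_params <- function(beta = 0, gamma = 1.5, pna = 0, pk = 0, pcl = 0,
                            inc = 0, ikc = 0, inkcc = 0, kb = 0) {
  p <- list(beta = beta, gamma = gamma, pna = pna, pk = pk, pcl = pcl,
            inc = inc, ikc = ikc, inkcc = inkcc, kb = kb)
  v <- unlist(p)
  if (any(!is.finite(v)) || any(v < 0))
    stop("all transport coefficients must be finite and >= 0")
  if (gamma <= 0) stop("'gamma' must be > 0")
  structure(p, class = "membrane_params")
}

#' @export
print.membrane_params <- function(x, ...) {
  cat("Membrane transport parameters:\n")
  cat(sprintf("  pump:     beta %g min^-1, gamma %g, kb %g min^-2\n",
              x$beta, x$gamma, x$kb))
  cat(sprintf("  channels: pna %g, pk %g, pcl %g min^-1\n",
              x$pna, x$pk, x$pcl))
  cat(sprintf("  cotransp: inc %g, ikc %g (ml/umol/min), inkcc %g (ml^3/umol^3/min)\n",
              x$inc, x$ikc, x$inkcc))
  invisible(x)
}

# replace named fields, validating the result
update_params <- function(params, overrides) {
  bad <- setdiff(names(overrides), .param_names)
  if (length(bad))
    stop("unknown parameter name(s): ", paste(bad, collapse = ", "))
  params[names(overrides)] <- overrides
  do.call(membrane_params, unclass(params))
}

#' Intracellular state of the model cell
#'
#' Builds a constraint-consistent initial state from intracellular
#' concentrations and the medium: the impermeant-osmolyte concentration
#' A/V and its mean valence z are derived so that osmotic balance and
#' electroneutrality hold exactly (see [derive_impermeant()]); the
#' impermeant amount A is normalized to 1 mmol, so the water volume V is
#' in ml per mmol of A (V identical to the V/A variable of the model).
#'
#' @param na,k,cl Intracellular concentrations in cell water (mM, > 0).
#' @param medium An [external_medium()].
#' @param t Time stamp (min).
#' @return An object of class `cell_state` with fields `na`, `k`, `cl` (mM),
#'   `V` (ml per mmol A), `z`, `t`, and membrane potential `u`
#'   (dimensionless) and `U` (mV) set to `NA` until solved.
#' @examples
#' cell_state(33, 152, 45, standard_medium())
#' @export
cell_state <- function(na, k, cl, medium, t = 0) {
  if (any(c(na, k, cl) <= 0)) stop("intracellular concentrations must be > 0")
  imp <- derive_impermeant(na, k, cl, medium)
  structure(list(t = t, na = na, k = k, cl = cl,
                 V = 1000 / imp$a_per_v, z = imp$z,
                 u = NA_real_, U = NA_real_),
            class = "cell_state")
}

#' @export
print.cell_state <- function(x, ...) {
  cat(sprintf("Cell state at t = %g min:\n", x$t))
  cat(sprintf("  [Na]i %.4g  [K]i %.4g  [Cl]i %.4g mM\n", x$na, x$k, x$cl))
  cat(sprintf("  V/A %.4g ml/mmol  (A/V*1000 = %.4g mM), z = %.4g\n",
              x$V, 1000 / x$V, x$z))
  if (is.finite(x$U)) cat(sprintf("  U = %.4g mV\n", x$U))
  else cat("  U not yet solved\n")
  invisible(x)
}

#' Piecewise parameter-change schedule
#'
#' An ordered list of instantaneous parameter overrides: the event at time
#' `t` replaces the named [membrane_params()] fields from that time onward
#' (stepwise change, no look-ahead). An override of `beta` resets the value
#' from which the linear `kb` decay is measured.
#'
#' @param times Event times (min), strictly increasing.
#' @param overrides List of named lists of parameter overrides, parallel to
#'   `times`.
#' @return An object of class `param_schedule`.
#' @examples
#' param_schedule(c(0, 60),
#'                list(list(pk = 0.03, pna = 0.003, pcl = 0.068, kb = 6.8e-5),
#'                     list(pk = 0.02)))
#' @export
param_schedule <- function(times = numeric(), overrides = list()) {
  if (length(times) != length(overrides))
    stop("'times' and 'overrides' must have the same length")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("schedule times must be strictly increasing")
  for (ov in overrides) {
    if (!length(ov) || is.null(names(ov)) || any(names(ov) == ""))
      stop("each override must be a named list of parameter values")
    bad <- setdiff(names(ov), .param_names)
    if (length(bad))
      stop("unknown parameter name(s) in schedule: ", paste(bad, collapse = ", "))
  }
  structure(list(times = as.numeric(times), overrides = overrides),
            class = "param_schedule")
}

#' @export
print.param_schedule <- function(x, ...) {
  if (!length(x$times)) {
    cat("Empty parameter schedule\n")
    return(invisible(x))
  }
  cat("Parameter schedule:\n")
  for (i in seq_along(x$times)) {
    ov <- x$overrides[[i]]
    cat(sprintf("  t = %g min: %s\n", x$times[i],
                paste(names(ov), unlist(ov), sep = " = ", collapse = ", ")))
  }
  invisible(x)
}
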