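# Conversions from raw measurements (buoyant density, flame photometry,
# ouabain-sensitive Rb+ influx) to model inputs.

#' Cell water content from buoyant density
#'
#' `v_prot = (1 - rho/rho_dry) / (protein_frac * (rho - 1))`, the water
#' volume per gram of cell protein inferred from the measured buoyant
#' density `rho`, the dry-mass density `rho_dry` (default 1.38 g/ml) and
#' the protein fraction of dry mass (default 0.72).
#'
#' @param rho Measured buoyant density (g/ml), in (1, rho_dry].
#' @param rho_dry Dry mass density (g/ml).
#' @param protein_frac Protein proportion of dry mass.
#' @return Water content (ml per g protein). Strictly decreasing in `rho`;
#'   zero at `rho = rho_dry`.
#' @examples
#' water_from_density(1.054) # ~ 6.08 ml/g
#' @export
water_from_density <- function(rho, rho_dry = 1.38, protein_frac = 0.72) {
  if (any(rho <= 1) || any(rho > rho_dry))
    stop("'rho' must lie in (1, rho_dry]")
  (1 - rho / rho_dry) / (protein_frac * (rho - 1))
}

#' Pump rate coefficient from ouabain-sensitive Rb+ influx
#'
#' The pump's total cation influx is estimated from the Rb+-borne fraction
#' by the bath composition during the assay, the pump Na+ efflux follows
#' from the Na/K stoichiometry `gamma`, and `beta` is the ratio of that
#' efflux to the cell Na+ content:
#' `beta = gamma * os_rb_influx * scale / na_content` with
#' `scale = (rbo + ko)/rbo` (convention `"total"`, default: Rb+ and K+
#' together carry the pump influx) or `scale = ko/rbo` (convention
#' `"k_only"`: the assay K+ concentration alone is scaled up).
#'
#' @param os_rb_influx Ouabain-sensitive Rb+ influx (umol min^-1, per the
#'   same base as `na_content`).
#' @param na_content Cell Na+ content (umol, same base).
#' @param rbo,ko Rb+ and K+ concentrations in the assay medium (mM).
#' @param gamma Pump Na/K flux stoichiometry.
#' @param convention Rb -> K scaling convention (see Details).
#' @return Pump rate coefficient beta (min^-1), with the convention used
#'   attached as attribute `"convention"`.
#' @examples
#' pump_beta_from_rb(0.2, 32) # ~ 0.0311 min^-1
#' @export
pump_beta_from_rb <- function(os_rb_influx, na_content, rbo = 2.5, ko = 5.8,
                              gamma = 1.5, convention = c("total", "k_only")) {
  convention <- match.arg(convention)
  stopifnot(os_rb_influx >= 0, rbo > 0, ko > 0, gamma > 0)
  if (na_content <= 0) stop("'na_content' must be > 0")
  scale <- if (convention == "total") (rbo + ko) / rbo else ko / rbo
  beta <- gamma * os_rb_influx * scale / na_content
  attr(beta, "convention") <- convention
  beta
}

#' Ion concentration from content and water per gram protein
#'
#' `concentration = content / water`: converts an ion content in umol per
#' gram of protein and a water content in ml per gram of protein into a
#' concentration in cell water (mM).
#'
#' @param content Ion content (umol per g protein).
#' @param water Water content (ml per g protein, > 0).
#' @return Concentration (mM).
#' @examples
#' ion_content_units(712, 6.08) # ~ 117 mM K+
#' @export
ion_content_units <- function(content, water) {
  if (any(water <= 0)) stop("'water' must be > 0")
  content / water
}
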