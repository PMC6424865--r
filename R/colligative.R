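# Concentration-dependent observables. All outputs are relative: the
# method-specific calibration constants (alpha for scattering, beta for
# sedimentation equilibrium, lambda for osmometry) are taken as exactly 1;
# absolute calibration is a user-supplied multiplier.

.div_tol <- 1e-6

denom_colligative <- function(Q, phi) {
  suppressWarnings(1 + phi_dlngamma_dphi(Q, phi))
}

#' Relative static light-scattering intensity
#'
#' \eqn{I(\phi) = \phi / (1 + \phi\, d\ln\gamma/d\phi)} in reduced units
#' (calibration constant \eqn{\alpha = 1}, \eqn{\phi} as concentration
#' proxy). For the ideal solution this is linear, \eqn{I = \phi}. Where the
#' denominator vanishes the scattering diverges, signalling a
#' liquid-liquid instability; points with `|denominator| < 1e-6` are
#' returned as `NA` with attribute `diverged`.
#'
#' @param Q An `sw_quartic` (or numeric `c(Q1..Q4)`).
#' @param phi Volume fraction(s).
#' @return Relative intensity; `NA` where flagged divergent.
#' @export
scattering_intensity <- function(Q, phi) {
  d <- denom_colligative(Q, phi)
  bad <- abs(d) < .div_tol
  out <- phi / d
  out[bad] <- NA_real_
  if (any(bad)) attr(out, "diverged") <- unname(bad)
  out
}

#' Apparent molar mass at sedimentation-diffusion equilibrium
#'
#' \eqn{M_{app}(\phi) = M / (1 + \phi\, d\ln\gamma/d\phi)}. Repulsion makes
#' \eqn{M_{app} < M}; net attraction makes it exceed \eqn{M}, diverging at
#' the same composition as the scattering intensity.
#'
#' @inheritParams scattering_intensity
#' @param M True molar mass (g/mol); default 1 returns the ratio
#'   \eqn{M_{app}/M}.
#' @return Apparent molar mass; `NA` where flagged divergent.
#' @export
apparent_molar_mass <- function(Q, phi, M = 1) {
  d <- denom_colligative(Q, phi)
  bad <- abs(d) < .div_tol
  out <- M / d
  out[bad] <- NA_real_
  if (any(bad)) attr(out, "diverged") <- unname(bad)
  out
}

#' Reduced osmotic pressure
#'
#' \eqn{\Pi/\lambda = \phi + \int_0^\phi \phi^* (d\ln\gamma/d\phi^*)
#' d\phi^*}, with the integral from [integral_term()]. The van 't Hoff limit
#' is \eqn{\Pi/\lambda = \phi}. Non-monotonic \eqn{\Pi(\phi)} is physically
#' unrealizable and marks a liquid-liquid phase transition.
#'
#' @inheritParams scattering_intensity
#' @return \eqn{\Pi/\lambda} in volume-fraction units.
#' @export
osmotic_pressure <- function(Q, phi) {
  phi + integral_term(Q, phi)
}

# d(Pi)/d(phi) = 1 + phi dlngamma/dphi -- shared with the phase module
dPi_dphi <- function(Q, phi) {
  suppressWarnings(denom_colligative(Q, phi))
}

#' Scattering divergence threshold
#'
#' The smallest \eqn{\phi > 0} at which
#' \eqn{1 + \phi\, d\ln\gamma/d\phi = 0}, i.e. where the scattered
#' intensity diverges and \eqn{d\Pi/d\phi} crosses zero. Returns `NA` if no
#' root exists below `phi_max` (solution stable throughout).
#'
#' @inheritParams scattering_intensity
#' @param phi_max Upper end of the search interval.
#' @return Volume fraction of divergence, or `NA`.
#' @export
divergence_phi <- function(Q, phi_max = 0.6) {
  Q <- as_quartic(Q)
  q <- Q$Q
  roots <- polyroot(c(1, q[1], 2 * q[2], 3 * q[3], 4 * q[4]))
  re <- Re(roots)[abs(Im(roots)) < 1e-8]
  re <- sort(re[re > 0 & re <= phi_max])
  if (length(re) == 0) NA_real_ else re[1]
}

#' Crowding factor of a reaction
#'
#' \eqn{\Gamma = \exp(\sum_{reactants} \ln\gamma - \sum_{products}
#' \ln\gamma)}, the non-ideality factor converting a thermodynamic
#' equilibrium constant into the apparent concentration-based one. For
#' two-state unfolding \eqn{N \rightleftharpoons U},
#' \eqn{\Gamma_{NU} = \gamma_N/\gamma_U}; for association
#' \eqn{A + B \rightleftharpoons AB},
#' \eqn{\Gamma_{AB} = \gamma_A\gamma_B/\gamma_{AB}}.
#'
#' @param lngamma Named numeric vector of \eqn{\ln\gamma} per species, from
#'   any activity model at the ambient composition.
#' @param reactants,products Character vectors of species names (repeat a
#'   name for stoichiometry > 1).
#' @return The dimensionless crowding factor \eqn{\Gamma}.
#' @examples
#' crowding_factor(c(N = 1, U = 3), reactants = "N", products = "U")
#' @export
crowding_factor <- function(lngamma, reactants, products) {
  need <- unique(c(reactants, products))
  missing <- setdiff(need, names(lngamma))
  if (length(missing) > 0)
    stop("missing ln(gamma) for species: ", paste(missing, collapse = ", "))
  exp(sum(lngamma[reactants]) - sum(lngamma[products]))
}

#' Colligative property curves on a grid
#'
#' Tabulates relative scattering intensity, apparent molar mass ratio and
#' reduced osmotic pressure for a quartic activity representation (or, via
#' `params`, for the Kihara+ model fitted on the standard grid).
#'
#' @param Q An `sw_quartic`, or `NULL` to fit one from `params`.
#' @param params An [sw_interaction()] (used when `Q` is `NULL`).
#' @param phi Grid of volume fractions.
#' @param sigma Hard-core diameter (Kihara+ path).
#' @return A data.frame with columns `phi`, `I_rel`, `Mapp_over_M`,
#'   `Pi_rel`, `diverged`.
#' @export
colligative_curve <- function(Q = NULL, params = NULL,
                              phi = seq(0.01, 0.4, by = 0.01), sigma = 1) {
  if (is.null(Q)) {
    if (is.null(params)) stop("supply either Q or params")
    Q <- fit_quartic(kihara_plus_curve(params, sigma))
  }
  d <- denom_colligative(Q, phi)
  diverged <- abs(d) < .div_tol
  data.frame(phi = phi,
             I_rel = ifelse(diverged, NA_real_, phi / d),
             Mapp_over_M = ifelse(diverged, NA_real_, 1 / d),
             Pi_rel = osmotic_pressure(Q, phi),
             diverged = diverged)
}
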