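# Concentration dependence of the thermodynamic activity coefficient.
# All functions work in reduced units: phi is the solute volume fraction,
# sigma the hard-core diameter, energies in kT.

#' Hard-sphere activity coefficient from scaled particle theory
#'
#' Excess chemical potential (in kT) of a hard sphere among identical hard
#' spheres, from the SPT compressibility factor
#' \eqn{Z(\phi) = (1 + \phi + \phi^2)/(1 - \phi)^3} via the thermodynamic
#' identity \eqn{\ln\gamma = (Z - 1) + \int_0^\phi (Z - 1)/\phi' d\phi'}:
#' \deqn{\ln\gamma_{SPT} = \frac{\phi(4 - 2\phi + \phi^2)}{(1-\phi)^3}
#'   + \frac{3}{2}\left[(1-\phi)^{-2} - 1\right] - \ln(1-\phi)}
#' The leading-order slope is \eqn{8\phi}, consistent with
#' \eqn{2 B_2^{HS} \rho}.
#'
#' @param phi Volume fraction(s) in `[0, 1)`; vectorized.
#' @return \eqn{\ln\gamma} (dimensionless).
#' @export
lngamma_spt_hs <- function(phi) {
  if (any(!is.finite(phi)) || any(phi < 0) || any(phi >= 1))
    stop("phi must lie in [0, 1)")
  phi * (4 - 2 * phi + phi^2) / (1 - phi)^3 +
    1.5 * ((1 - phi)^-2 - 1) - log1p(-phi)
}

#' SPT compressibility factor of the hard-sphere fluid
#'
#' \eqn{Z(\phi) = (1 + \phi + \phi^2)/(1 - \phi)^3}.
#'
#' @inheritParams lngamma_spt_hs
#' @return Compressibility factor \eqn{Z = \Pi/(\rho kT)}.
#' @export
z_spt_hs <- function(phi) {
  if (any(!is.finite(phi)) || any(phi < 0) || any(phi >= 1))
    stop("phi must lie in [0, 1)")
  (1 + phi + phi^2) / (1 - phi)^3
}

# d(ln gamma_SPT)/dphi, analytic: Z'(phi) + (Z - 1)/phi
dlngamma_spt_dphi <- function(phi) {
  (4 + 4 * phi + phi^2) / (1 - phi)^4 +
    (4 - 2 * phi + phi^2) / (1 - phi)^3
}

#' Hard-sphere activity coefficient from the Carnahan-Starling equation
#'
#' Alternative hard-core reference (never the default):
#' \eqn{\ln\gamma_{CS} = \phi(8 - 9\phi + 3\phi^2)/(1-\phi)^3}.
#'
#' @inheritParams lngamma_spt_hs
#' @return \eqn{\ln\gamma} (dimensionless).
#' @export
lngamma_cs_hs <- function(phi) {
  if (any(!is.finite(phi)) || any(phi < 0) || any(phi >= 1))
    stop("phi must lie in [0, 1)")
  phi * (8 - 9 * phi + 3 * phi^2) / (1 - phi)^3
}

dlngamma_cs_dphi <- function(phi) {
  (8 - 2 * phi) / (1 - phi)^4
}

#' Soft (attraction) contribution to ln gamma
#'
#' Truncated virial form
#' \eqn{\ln\gamma_{soft} = 2 B_{2,soft}\, \rho + (3/2) B_{3,soft}\, \rho^2},
#' with \eqn{\rho = 6\phi/(\pi\sigma^3)} the number density and the soft
#' virials from [soft_components()]. The factors 2 and 3/2 implement the
#' McMillan-Mayer convention relating osmotic virials to the activity
#' expansion; it is the unique convention under which the hard-sphere limit
#' reproduces the SPT leading slope of 8.
#'
#' @inheritParams lngamma_spt_hs
#' @param params An [sw_interaction()].
#' @param sigma Hard-core diameter.
#' @return \eqn{\ln\gamma_{soft}} (dimensionless); identically 0 at
#'   `eps_star = 0`.
#' @export
lngamma_soft <- function(phi, params, sigma = 1) {
  if (any(!is.finite(phi)) || any(phi < 0) || any(phi >= 1))
    stop("phi must lie in [0, 1)")
  soft <- soft_components(params, sigma)
  rho <- 6 * phi / (pi * sigma^3)
  2 * soft$B2_soft * rho + 1.5 * soft$B3_soft * rho^2
}

dlngamma_soft_dphi <- function(phi, params, sigma = 1) {
  soft <- soft_components(params, sigma)
  k <- 6 / (pi * sigma^3)
  2 * soft$B2_soft * k + 3 * soft$B3_soft * k^2 * phi
}

#' Kihara+ activity coefficient
#'
#' The hybrid analytical model:
#' \eqn{\ln\gamma = \ln\gamma_{hard} + \ln\gamma_{soft}}, with the hard term
#' from scaled particle theory ([lngamma_spt_hs()]; Carnahan-Starling
#' available as an option) and the soft term from the steric-subtracted
#' square-well virials ([lngamma_soft()]). Reduces exactly to the hard
#' reference at `eps_star = 0`.
#'
#' @inheritParams lngamma_soft
#' @param hard Hard-core reference, `"spt"` (default) or `"cs"`.
#' @return \eqn{\ln\gamma} (dimensionless).
#' @export
lngamma_kihara_plus <- function(phi, params, sigma = 1,
                                hard = c("spt", "cs")) {
  hard <- match.arg(hard)
  h <- if (hard == "spt") lngamma_spt_hs(phi) else lngamma_cs_hs(phi)
  h + lngamma_soft(phi, params, sigma)
}

#' Analytic derivative of the Kihara+ ln gamma
#'
#' \eqn{d\ln\gamma/d\phi} from the closed forms of both terms; the exact
#' alternative to differentiating the quartic fit.
#'
#' @inheritParams lngamma_kihara_plus
#' @return \eqn{d\ln\gamma/d\phi}.
#' @export
dlngamma_kihara_plus_dphi <- function(phi, params, sigma = 1,
                                      hard = c("spt", "cs")) {
  hard <- match.arg(hard)
  h <- if (hard == "spt") dlngamma_spt_dphi(phi) else dlngamma_cs_dphi(phi)
  h + dlngamma_soft_dphi(phi, params, sigma)
}

#' Activity-coefficient curve on a volume-fraction grid
#'
#' Bundles a strictly increasing `phi` grid with `lngamma` values and a
#' source label into an `sw_activity_curve` (a data.frame).
#'
#' @param phi Strictly increasing volume fractions, all in `(0, 1)`.
#' @param lngamma Matching \eqn{\ln\gamma} values (finite).
#' @param source One of `"spt"`, `"kihara_plus"`, `"simulation"`, `"user"`.
#' @return An `sw_activity_curve` data.frame with columns `phi`, `lngamma`.
#' @export
activity_curve <- function(phi, lngamma,
                           source = c("user", "spt", "kihara_plus",
                                      "simulation")) {
  source <- match.arg(source)
  stopifnot(length(phi) == length(lngamma))
  if (any(!is.finite(phi)) || any(phi <= 0) || any(phi >= 1))
    stop("phi grid must lie in (0, 1)")
  if (any(diff(phi) <= 0)) stop("phi grid must be strictly increasing")
  if (any(!is.finite(lngamma))) stop("lngamma must be finite on the grid")
  structure(data.frame(phi = phi, lngamma = lngamma),
            source = source,
            class = c("sw_activity_curve", "data.frame"))
}

#' Kihara+ activity curve on the standard fitting grid
#'
#' Convenience wrapper evaluating [lngamma_kihara_plus()] on
#' `phi = seq(step, phi_max, by = step)`.
#'
#' @inheritParams lngamma_kihara_plus
#' @param phi_max,step Grid upper end and spacing (defaults 0.4 and 0.01,
#'   the fitting window used throughout).
#' @return An [activity_curve()] with source `"kihara_plus"`.
#' @export
kihara_plus_curve <- function(params, sigma = 1, phi_max = 0.4, step = 0.01,
                              hard = "spt") {
  phi <- seq(step, phi_max, by = step)
  activity_curve(phi, lngamma_kihara_plus(phi, params, sigma, hard),
                 source = "kihara_plus")
}

#' Quartic representation of ln gamma
#'
#' Zero-intercept linear least squares of
#' \eqn{\ln\gamma = Q_1\phi + Q_2\phi^2 + Q_3\phi^3 + Q_4\phi^4}
#' on an activity curve. The quartic is the working representation from
#' which all colligative properties and phase constructions are computed.
#'
#' @param curve An [activity_curve()] (or any data.frame with `phi` and
#'   `lngamma` columns) with at least 8 points inside the fit domain.
#' @param phi_min,phi_max Fit domain (default `(0, 0.4]`).
#' @return An object of class `sw_quartic`: list with `Q` (named numeric
#'   `Q1..Q4`), `fit_domain`, `fit_residual` (RMS) and `n_points`.
#' @export
fit_quartic <- function(curve, phi_min = 0, phi_max = 0.4) {
  stopifnot(all(c("phi", "lngamma") %in% names(curve)))
  keep <- curve$phi > phi_min & curve$phi <= phi_max
  phi <- curve$phi[keep]
  y <- curve$lngamma[keep]
  if (length(phi) < 8) stop("need at least 8 grid points inside the fit domain")
  X <- cbind(phi, phi^2, phi^3, phi^4)
  qrX <- qr(X)
  if (qrX$rank < 4) stop("degenerate phi grid: singular quartic design")
  Q <- qr.coef(qrX, y)
  resid <- y - X %*% Q
  structure(list(Q = stats::setNames(as.numeric(Q), paste0("Q", 1:4)),
                 fit_domain = c(phi_min = phi_min, phi_max = phi_max),
                 fit_residual = sqrt(mean(resid^2)),
                 n_points = length(phi)),
            class = "sw_quartic")
}

#' @export
print.sw_quartic <- function(x, ...) {
  cat("Quartic ln(gamma) representation\n")
  cat(sprintf("  Q1 = %.6g  Q2 = %.6g  Q3 = %.6g  Q4 = %.6g\n",
              x$Q[1], x$Q[2], x$Q[3], x$Q[4]))
  cat(sprintf("  fit domain (%g, %g], RMS residual %.3g (%d points)\n",
              x$fit_domain[1], x$fit_domain[2], x$fit_residual, x$n_points))
  invisible(x)
}

as_quartic <- function(Q) {
  if (inherits(Q, "sw_quartic")) return(Q)
  if (is.numeric(Q) && length(Q) == 4)
    return(structure(list(Q = stats::setNames(as.numeric(Q), paste0("Q", 1:4)),
                          fit_domain = c(phi_min = 0, phi_max = 0.4),
                          fit_residual = 0, n_points = 0L),
                     class = "sw_quartic"))
  stop("expected an sw_quartic or a numeric vector of 4 coefficients")
}

flag_extrapolation <- function(Q, phi, value) {
  extra <- phi > Q$fit_domain["phi_max"] | phi < Q$fit_domain["phi_min"]
  if (any(extra)) {
    warning("evaluating quartic outside its fit domain", call. = FALSE)
    attr(value, "extrapolated") <- unname(extra)
  }
  value
}

#' Evaluate the quartic ln gamma
#'
#' @param Q An `sw_quartic` (from [fit_quartic()]) or numeric `c(Q1..Q4)`.
#' @param phi Volume fraction(s).
#' @return \eqn{Q_1\phi + Q_2\phi^2 + Q_3\phi^3 + Q_4\phi^4}; evaluation
#'   outside the fit domain warns and carries an `extrapolated` attribute.
#' @export
eval_quartic <- function(Q, phi) {
  Q <- as_quartic(Q)
  q <- unname(Q$Q)
  flag_extrapolation(Q, phi,
                     q[1] * phi + q[2] * phi^2 + q[3] * phi^3 + q[4] * phi^4)
}

#' The thermodynamic slope phi * d(ln gamma)/d(phi)
#'
#' The quantity controlling all three colligative observables
#' (note \eqn{c\, d\ln\gamma/dc = \phi\, d\ln\gamma/d\phi}):
#' \deqn{\phi \frac{d\ln\gamma}{d\phi} = Q_1\phi + 2Q_2\phi^2 + 3Q_3\phi^3
#'   + 4Q_4\phi^4}
#'
#' @inheritParams eval_quartic
#' @return Dimensionless; 0 at `phi = 0`.
#' @export
phi_dlngamma_dphi <- function(Q, phi) {
  Q <- as_quartic(Q)
  q <- unname(Q$Q)
  flag_extrapolation(Q, phi,
                     q[1] * phi + 2 * q[2] * phi^2 + 3 * q[3] * phi^3 +
                       4 * q[4] * phi^4)
}

#' Integral term of the osmotic pressure
#'
#' \deqn{\int_0^\phi \phi^* \frac{d\ln\gamma}{d\phi^*} d\phi^*
#'   = \frac{1}{2}Q_1\phi^2 + \frac{2}{3}Q_2\phi^3 + \frac{3}{4}Q_3\phi^4
#'   + \frac{4}{5}Q_4\phi^5}
#'
#' @inheritParams eval_quartic
#' @return Dimensionless; 0 at `phi = 0`.
#' @export
integral_term <- function(Q, phi) {
  Q <- as_quartic(Q)
  q <- unname(Q$Q)
  flag_extrapolation(Q, phi,
                     q[1] * phi^2 / 2 + 2 * q[2] * phi^3 / 3 +
                       3 * q[3] * phi^4 / 4 + 4 * q[4] * phi^5 / 5)
}
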