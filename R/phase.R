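# Liquid-liquid phase separation of the square-well fluid: spinodal,
# binodal, critical point, full diagrams, lever rule and reduced
# (temperature-scaled) coexistence curves.
#
# All constructions operate on an "activity model": an object that yields a
# quartic ln(gamma) representation for any requested well depth eps*. The
# default is the Kihara+ model refitted on the standard grid for each eps*
# (the pipeline behind the reference phase diagrams); tabulated simulation
# results enter through table_activity_model().

#' Kihara+ activity model over the well-depth axis
#'
#' For a fixed well range `L`, yields the quartic representation of the
#' Kihara+ \eqn{\ln\gamma(\phi)} for any well depth, fitted on
#' `phi = seq(step, phi_max, by = step)`. Fits are cached per `eps_star`.
#'
#' @param L Well range (`>= 1`).
#' @param sigma Hard-core diameter.
#' @param hard Hard-core reference, `"spt"` (default) or `"cs"`.
#' @param phi_max,step Fitting grid (defaults `(0, 0.4]` step 0.01).
#' @return An object of class `sw_model`.
#' @export
kihara_activity_model <- function(L, sigma = 1, hard = "spt",
                                  phi_max = 0.4, step = 0.01) {
  stopifnot(L >= 1)
  cache <- new.env(parent = emptyenv())
  quartic_fun <- function(eps_star) {
    key <- sprintf("%.15g", eps_star)
    if (!is.null(cache[[key]])) return(cache[[key]])
    p <- sw_interaction(L, eps_star)
    Q <- fit_quartic(kihara_plus_curve(p, sigma, phi_max, step, hard))
    cache[[key]] <- Q
    Q
  }
  # exact Kihara+ thermodynamics, used for coexistence branches that leave
  # the quartic fit window: ln gamma_soft = a1 phi + a2 phi^2, so
  # Pi = phi Z_hard(phi) + a1 phi^2 / 2 + (2/3) a2 phi^3
  soft_coefs <- function(eps_star) {
    soft <- soft_components(sw_interaction(L, eps_star), sigma)
    k <- 6 / (pi * sigma^3)
    c(a1 = 2 * soft$B2_soft * k, a2 = 1.5 * soft$B3_soft * k^2)
  }
  exact <- list(
    lngamma = function(phi, eps_star)
      lngamma_kihara_plus(phi, sw_interaction(L, eps_star), sigma, hard),
    dlngamma = function(phi, eps_star)
      dlngamma_kihara_plus_dphi(phi, sw_interaction(L, eps_star), sigma, hard),
    Pi = function(phi, eps_star) {
      a <- soft_coefs(eps_star)
      zh <- if (hard == "spt") z_spt_hs(phi) else
        (1 + phi + phi^2 - phi^3) / (1 - phi)^3
      phi * zh + a[["a1"]] * phi^2 / 2 + 2 * a[["a2"]] * phi^3 / 3
    })
  structure(list(L = L, sigma = sigma, hard = hard,
                 type = "kihara_plus", quartic_fun = quartic_fun,
                 exact = exact),
            class = "sw_model")
}

#' Activity model from tabulated quartic coefficients
#'
#' Builds an `sw_model` from quartic coefficients obtained at a set of well
#' depths (typically fits to simulation-derived \eqn{\ln\gamma} curves).
#' Each coefficient \eqn{Q_i(\epsilon^*)} is interpolated by a natural
#' cubic spline; the well-depth grid must bracket any critical point to be
#' located.
#'
#' @param eps_values Well depths at which coefficients were obtained
#'   (at least 3, strictly monotone).
#' @param Q_matrix Numeric matrix, one row per `eps_values` entry, columns
#'   `Q1..Q4`.
#' @param L Well range the table refers to (metadata).
#' @return An object of class `sw_model`.
#' @export
table_activity_model <- function(eps_values, Q_matrix, L = NA_real_) {
  Q_matrix <- as.matrix(Q_matrix)
  stopifnot(length(eps_values) >= 3, nrow(Q_matrix) == length(eps_values),
            ncol(Q_matrix) == 4)
  ord <- order(eps_values)
  eps_values <- eps_values[ord]
  Q_matrix <- Q_matrix[ord, , drop = FALSE]
  splines <- lapply(1:4, function(j)
    stats::splinefun(eps_values, Q_matrix[, j], method = "natural"))
  quartic_fun <- function(eps_star) {
    q <- vapply(splines, function(s) s(eps_star), numeric(1))
    as_quartic(q)
  }
  structure(list(L = L, sigma = 1, hard = NA_character_,
                 type = "table", eps_range = range(eps_values),
                 quartic_fun = quartic_fun, exact = NULL),
            class = "sw_model")
}

#' @export
print.sw_model <- function(x, ...) {
  cat("Square-well activity model (", x$type, "), L = ", x$L, "\n", sep = "")
  invisible(x)
}

# quartic evaluation helpers that suppress extrapolation warnings (solvers
# legitimately probe beyond the fit window; results carry flags instead)
q_lngamma <- function(Q, phi) suppressWarnings(as.numeric(eval_quartic(Q, phi)))
q_mu <- function(Q, phi) log(phi) + q_lngamma(Q, phi)
q_Pi <- function(Q, phi) suppressWarnings(as.numeric(phi + integral_term(Q, phi)))
q_dPi <- function(Q, phi) suppressWarnings(as.numeric(1 + phi_dlngamma_dphi(Q, phi)))
q_d2Pi <- function(Q, phi) {
  q <- unname(as_quartic(Q)$Q)
  q[1] + 4 * q[2] * phi + 9 * q[3] * phi^2 + 16 * q[4] * phi^3
}

# mu / Pi / dPi accessors for a model at fixed eps*, on the quartic or the
# exact (closed-form Kihara+) path
thermo_funs <- function(model, eps_star, method) {
  if (method == "exact") {
    if (is.null(model$exact))
      stop("exact thermodynamics not available for this model")
    list(mu = function(p) log(p) + model$exact$lngamma(p, eps_star),
         Pi = function(p) model$exact$Pi(p, eps_star),
         dPi = function(p) 1 + p * model$exact$dlngamma(p, eps_star))
  } else {
    Q <- model$quartic_fun(eps_star)
    list(mu = function(p) q_mu(Q, p),
         Pi = function(p) q_Pi(Q, p),
         dPi = function(p) q_dPi(Q, p))
  }
}

#' Spinodal compositions
#'
#' The two roots of \eqn{d\Pi/d\phi = 1 + \phi\, d\ln\gamma/d\phi = 0}
#' bracketing the thermodynamically unstable region. On the default quartic
#' path they are real roots of the quartic \eqn{d\Pi/d\phi} polynomial; on
#' the exact path (`method = "exact"`, closed-form Kihara+ thermodynamics,
#' useful where the unstable region extends past the quartic fit window)
#' they come from a dense sign-change scan refined by bisection. Returns
#' `NULL` when the osmotic pressure is monotone (no instability at this
#' well depth).
#'
#' @param model An `sw_model`.
#' @param eps_star Well depth (kT units).
#' @param phi_max Upper end of the physically meaningful search window
#'   (default 0.6 on the quartic path, 0.72 on the exact path).
#' @param method `"quartic"` (default) or `"exact"`.
#' @return `NULL`, or a list with `phi_lower_star` and `phi_upper_star`.
#' @export
spinodal <- function(model, eps_star, phi_max = NULL,
                     method = c("quartic", "exact")) {
  method <- match.arg(method)
  if (is.null(phi_max)) phi_max <- if (method == "exact") 0.72 else 0.6
  if (method == "quartic") {
    Q <- model$quartic_fun(eps_star)
    q <- Q$Q
    roots <- polyroot(c(1, q[1], 2 * q[2], 3 * q[3], 4 * q[4]))
    # tangency at the critical point shows up as a conjugate pair with a
    # tiny imaginary part, so the tolerance is loose relative to machine
    # precision
    re <- Re(roots)[abs(Im(roots)) < 1e-6]
    re <- sort(re[re > 0 & re <= phi_max])
  } else {
    th <- thermo_funs(model, eps_star, "exact")
    grid <- seq(1e-4, phi_max, by = 1e-3)
    v <- th$dPi(grid)
    idx <- which(v[-1] * v[-length(v)] < 0)
    re <- vapply(idx, function(i)
      stats::uniroot(th$dPi, c(grid[i], grid[i + 1]), tol = 1e-12)$root,
      numeric(1))
  }
  if (length(re) == 0) return(NULL)
  if (length(re) > 2)
    stop("more than two spinodal roots in (0, ", phi_max,
         "): model misuse")
  if (length(re) == 1)
    stop("single spinodal root in (0, ", phi_max,
         "): unstable region extends past the search window")
  list(phi_lower_star = re[1], phi_upper_star = re[2])
}

#' Binodal (coexistence) compositions
#'
#' The pair \eqn{\phi_{dil} < \phi_{conc}} satisfying simultaneous equality
#' of osmotic pressure \eqn{\Pi(\phi_1) = \Pi(\phi_2)} and chemical
#' potential \eqn{\ln\phi_1 + \ln\gamma(\phi_1) = \ln\phi_2 +
#' \ln\gamma(\phi_2)}. Solved by a nested bracketing construction (the
#' chemical potential is inverted on each stable branch, then the pressure
#' mismatch is driven to zero), followed by a two-dimensional Newton polish.
#'
#' @inheritParams spinodal
#' @param phi_hi Upper bound for the concentrated branch.
#' @param tol Convergence tolerance on both equalities.
#' @param method `"auto"` (default; quartic construction, switching to the
#'   exact closed-form Kihara+ thermodynamics when the concentrated branch
#'   leaves the quartic fit window), `"quartic"`, or `"exact"`.
#' @return `NULL` if no spinodal exists; otherwise a list with
#'   `phi_dil_eq`, `phi_conc_eq`, `mu`, `Pi`, `eps_star`, the `method`
#'   actually used and logical `extrapolated` (concentrated branch beyond
#'   the quartic fit domain).
#' @export
binodal <- function(model, eps_star, phi_hi = NULL, tol = 1e-10,
                    method = c("auto", "quartic", "exact")) {
  method <- match.arg(method)
  if (method == "auto") {
    res <- tryCatch(binodal(model, eps_star, phi_hi, tol, "quartic"),
                    error = function(e) e)
    switch_exact <- (inherits(res, "error") ||
                       (!is.null(res) && isTRUE(res$extrapolated))) &&
      !is.null(model$exact)
    if (!switch_exact) {
      if (inherits(res, "error")) stop(res)
      return(res)
    }
    return(binodal(model, eps_star, phi_hi, tol, "exact"))
  }
  if (is.null(phi_hi)) phi_hi <- if (method == "exact") 0.74 else 0.85
  sp <- spinodal(model, eps_star, method = method)
  if (is.null(sp)) return(NULL)
  th <- thermo_funs(model, eps_star, method)
  sl <- sp$phi_lower_star
  su <- sp$phi_upper_star
  mu <- th$mu
  Pi <- th$Pi
  mu_sl <- mu(sl); mu_su <- mu(su)
  span <- mu_sl - mu_su
  m_lo <- mu_su + 1e-8 * span
  m_hi <- min(mu_sl - 1e-8 * span, mu(phi_hi) - 1e-8 * span)
  pair_at <- function(m) {
    # mu -> -Inf as phi -> 0 with ln(gamma) -> 0, so exp(m - 5) always
    # undershoots the dilute root
    lo <- min(1e-10, exp(m - 5))
    p1 <- stats::uniroot(function(p) mu(p) - m, c(lo, sl),
                         tol = 1e-14)$root
    p2 <- stats::uniroot(function(p) mu(p) - m, c(su, phi_hi),
                         tol = 1e-14)$root
    c(p1, p2)
  }
  g <- function(m) { p <- pair_at(m); Pi(p[2]) - Pi(p[1]) }
  g_lo <- g(m_lo); g_hi <- g(m_hi)
  if (g_lo * g_hi > 0)
    stop(sprintf(paste0("binodal bracketing failed at eps* = %.4f: ",
                        "Pi mismatch %.3e at mu = %.6f and %.3e at mu = %.6f"),
                 eps_star, g_lo, m_lo, g_hi, m_hi))
  m_star <- stats::uniroot(g, c(m_lo, m_hi), tol = 1e-13)$root
  p <- pair_at(m_star)
  # Newton polish on (Pi equality, mu equality)
  for (it in 1:50) {
    F1 <- Pi(p[2]) - Pi(p[1])
    F2 <- mu(p[2]) - mu(p[1])
    if (abs(F1) < tol && abs(F2) < tol) break
    d1 <- th$dPi(p[1]); d2 <- th$dPi(p[2])
    J <- rbind(c(-d1, d2), c(-d1 / p[1], d2 / p[2]))
    step <- tryCatch(solve(J, -c(F1, F2)), error = function(e) NULL)
    if (is.null(step)) break
    p <- p + step
    if (p[1] <= 0 || p[1] >= sl || p[2] <= su) { p <- pair_at(m_star); break }
  }
  list(phi_dil_eq = p[1], phi_conc_eq = p[2],
       mu = mu(p[1]), Pi = Pi(p[1]), eps_star = eps_star,
       method = method,
       extrapolated = unname(p[2] > 0.4))
}

#' Binodal by Maxwell equal-area construction
#'
#' Independent route to the coexistence pair: finds the pressure
#' \eqn{\Pi^*} at which the signed area
#' \eqn{\int_{\phi_1}^{\phi_2} (\Pi(\phi) - \Pi^*)\, d(-1/\phi)} between
#' the non-monotonic isotherm and the horizontal tie line vanishes (the
#' Maxwell construction in the \eqn{(\Pi, -1/\phi)} plane, where equal
#' areas are equivalent to equal chemical potentials). Used as a
#' cross-check of [binodal()].
#'
#' @inheritParams binodal
#' @return As [binodal()] (without the Newton-polish metadata).
#' @export
binodal_maxwell <- function(model, eps_star, phi_hi = 0.85) {
  sp <- spinodal(model, eps_star)
  if (is.null(sp)) return(NULL)
  Q <- model$quartic_fun(eps_star)
  q <- Q$Q
  Pi <- function(p) q_Pi(Q, p)
  outer_roots <- function(Pstar) {
    roots <- polyroot(c(-Pstar, 1, q[1] / 2, 2 * q[2] / 3, 3 * q[3] / 4,
                        4 * q[4] / 5))
    re <- Re(roots)[abs(Im(roots)) < 1e-8]
    re <- sort(re[re > 0 & re <= phi_hi])
    if (length(re) < 2) return(NULL)
    c(re[1], re[length(re)])
  }
  area <- function(Pstar) {
    r <- outer_roots(Pstar)
    if (is.null(r)) return(NA_real_)
    stats::integrate(function(p) (Pi(p) - Pstar) / p^2, r[1], r[2],
                     rel.tol = 1e-12, subdivisions = 500L)$value
  }
  P_lo <- max(Pi(sp$phi_upper_star), 0) + 1e-12
  P_hi <- Pi(sp$phi_lower_star) - 1e-12
  P_star <- stats::uniroot(area, c(P_lo + 1e-9 * (P_hi - P_lo), P_hi),
                           tol = 1e-14)$root
  r <- outer_roots(P_star)
  list(phi_dil_eq = r[1], phi_conc_eq = r[2], Pi = P_star,
       eps_star = eps_star)
}

#' Critical point of liquid-liquid phase separation
#'
#' The composition and well depth at which the first and second
#' \eqn{\phi}-derivatives of the osmotic pressure vanish simultaneously:
#' the apex where binodal and spinodal meet. Located by a bisection scan
#' over the well depth (tracking the minimum of \eqn{d\Pi/d\phi}) followed
#' by a two-dimensional Newton iteration with numerical
#' \eqn{\epsilon^*}-derivatives.
#'
#' @param model An `sw_model`.
#' @param phi_box Composition search interval.
#' @param eps_box Well-depth search interval (must bracket the critical
#'   depth).
#' @return An object of class `sw_critical_point`: list with `phi_crit` and
#'   `eps_crit`.
#' @export
critical_point <- function(model, phi_box = c(0.02, 0.35),
                           eps_box = c(-2.5, -0.3)) {
  phis <- seq(phi_box[1], phi_box[2], length.out = 200L)
  min_dPi <- function(eps) {
    Q <- model$quartic_fun(eps)
    min(q_dPi(Q, phis))
  }
  f_lo <- min_dPi(eps_box[1]); f_hi <- min_dPi(eps_box[2])
  if (f_lo * f_hi > 0)
    stop("no critical point in the search box: min dPi/dphi = ",
         signif(f_lo, 4), " at eps* = ", eps_box[1], " and ",
         signif(f_hi, 4), " at eps* = ", eps_box[2])
  eps0 <- stats::uniroot(min_dPi, eps_box, tol = 1e-9)$root
  Q0 <- model$quartic_fun(eps0)
  phi0 <- phis[which.min(q_dPi(Q0, phis))]
  # Newton polish on (dPi/dphi, d2Pi/dphi2) in (phi, eps*)
  x <- c(phi0, eps0)
  Fv <- function(x) {
    Q <- model$quartic_fun(x[2])
    c(q_dPi(Q, x[1]), q_d2Pi(Q, x[1]))
  }
  converged <- FALSE
  for (it in 1:100) {
    f0 <- Fv(x)
    if (max(abs(f0)) < 1e-12) { converged <- TRUE; break }
    h <- 1e-7
    J <- cbind((Fv(x + c(h, 0)) - f0) / h, (Fv(x + c(0, h)) - f0) / h)
    step <- tryCatch(solve(J, -f0), error = function(e) NULL)
    if (is.null(step)) break
    # damp steps that would leave the search region
    while (x[1] + step[1] <= 0 || x[1] + step[1] >= 0.9) step <- step / 2
    x <- x + step
    if (max(abs(step)) < 1e-13) { converged <- TRUE; break }
  }
  if (!converged && max(abs(Fv(x))) > 1e-8)
    stop("critical-point Newton iteration did not converge")
  structure(list(phi_crit = x[1], eps_crit = x[2]),
            class = "sw_critical_point")
}

#' @export
print.sw_critical_point <- function(x, ...) {
  cat(sprintf("Critical point: phi_crit = %.4f, eps*_crit = %.4f\n",
              x$phi_crit, x$eps_crit))
  invisible(x)
}

#' Liquid-liquid phase diagram
#'
#' Computes binodal and spinodal compositions over a grid of well depths
#' below the critical depth, plus the critical point and polynomial fits
#' of \eqn{\epsilon^*} against \eqn{\phi} through the binodal and spinodal
#' point sets (the curves drawn through such diagrams).
#'
#' @param model An `sw_model`.
#' @param eps_grid Well depths to analyse; default
#'   `seq(eps_crit - 0.6, eps_crit - 0.02, by = 0.02)`.
#' @param fit_degree Degree of the polynomial fits (default 4).
#' @param ... Passed to [critical_point()].
#' @return An object of class `sw_phase_diagram`: list with `L`, `points`
#'   (data.frame: `eps_star`, `phi_dil_eq`, `phi_lower_star`,
#'   `phi_upper_star`, `phi_conc_eq`, `extrapolated`, `note`), `critical`,
#'   `binodal_fit`, `spinodal_fit` (polynomial coefficients, constant term
#'   first) and `failures` (character).
#' @export
phase_diagram <- function(model, eps_grid = NULL, fit_degree = 4, ...) {
  crit <- critical_point(model, ...)
  if (is.null(eps_grid))
    eps_grid <- seq(crit$eps_crit - 0.6, crit$eps_crit - 0.02, by = 0.02)
  eps_grid <- sort(eps_grid)
  rows <- list(); failures <- character()
  for (eps in eps_grid) {
    row <- tryCatch({
      bn <- binodal(model, eps, method = "auto")
      sp <- if (is.null(bn)) NULL else
        spinodal(model, eps, method = bn$method)
      if (is.null(sp) || is.null(bn)) {
        failures <- c(failures,
                      sprintf("eps* = %.4f: no phase separation", eps))
        NULL
      } else {
        data.frame(eps_star = eps,
                   phi_dil_eq = bn$phi_dil_eq,
                   phi_lower_star = sp$phi_lower_star,
                   phi_upper_star = sp$phi_upper_star,
                   phi_conc_eq = bn$phi_conc_eq,
                   method = bn$method,
                   extrapolated = bn$extrapolated)
      }
    }, error = function(e) {
      failures <<- c(failures, sprintf("eps* = %.4f: %s", eps,
                                       conditionMessage(e)))
      NULL
    })
    if (!is.null(row)) rows[[length(rows) + 1]] <- row
  }
  points <- if (length(rows)) do.call(rbind, rows) else
    data.frame(eps_star = numeric(), phi_dil_eq = numeric(),
               phi_lower_star = numeric(), phi_upper_star = numeric(),
               phi_conc_eq = numeric(), method = character(), extrapolated = logical())
  # Fitted curves describe the diagram around its apex: points whose
  # concentrated branch left the quartic window (flagged extrapolated, deep
  # quench) are kept in the table but excluded from the polynomial fits,
  # and the critical point, the common apex of both curves, anchors them.
  fit_pts <- points[!points$extrapolated, , drop = FALSE]
  fit_branch <- function(phi, eps) {
    phi <- c(phi, crit$phi_crit)
    eps <- c(eps, crit$eps_crit)
    if (length(phi) <= fit_degree) return(NULL)
    stats::lm.fit(outer(phi, 0:fit_degree, `^`), eps)$coefficients
  }
  binodal_fit <- fit_branch(c(fit_pts$phi_dil_eq, fit_pts$phi_conc_eq),
                            rep(fit_pts$eps_star, 2))
  spinodal_fit <- fit_branch(c(fit_pts$phi_lower_star, fit_pts$phi_upper_star),
                             rep(fit_pts$eps_star, 2))
  structure(list(L = model$L, points = points, critical = crit,
                 binodal_fit = binodal_fit, spinodal_fit = spinodal_fit,
                 fit_degree = fit_degree, failures = failures),
            class = "sw_phase_diagram")
}

#' @export
print.sw_phase_diagram <- function(x, ...) {
  cat("Square-well phase diagram, L =", x$L, "\n")
  print(x$critical)
  cat(" ", nrow(x$points), "coexistence points;",
      length(x$failures), "failed grid points\n")
  invisible(x)
}

#' Apex of a fitted phase-boundary polynomial
#'
#' Location and height of the maximum of a polynomial
#' \eqn{\epsilon^*(\phi)} fit (as stored in an `sw_phase_diagram`), for
#' consistency checks against the critical point.
#'
#' @param coefs Polynomial coefficients, constant term first.
#' @param interval Composition interval to search.
#' @return List with `phi` (arg max) and `eps_star` (max value).
#' @export
fit_apex <- function(coefs, interval = c(0.01, 0.6)) {
  f <- function(p) as.numeric(outer(p, seq_along(coefs) - 1, `^`) %*% coefs)
  opt <- stats::optimize(f, interval, maximum = TRUE)
  list(phi = opt$maximum, eps_star = opt$objective)
}

#' Lever rule
#'
#' Volume fraction of the concentrated phase for a demixed solution of
#' total composition `phi_total`:
#' \eqn{f_{conc} = (\phi - \phi_{dil}) / (\phi_{conc} - \phi_{dil})}.
#'
#' @param phi_total Total solute volume fraction, inside the binodal.
#' @param point A binodal pair: anything with `phi_dil_eq` and
#'   `phi_conc_eq` entries (e.g. a [binodal()] result or a phase-diagram
#'   row).
#' @return Fraction in `[0, 1]`.
#' @export
lever_rule <- function(phi_total, point) {
  lo <- point$phi_dil_eq; hi <- point$phi_conc_eq
  if (phi_total < lo || phi_total > hi)
    stop("phi_total outside the coexistence region [", signif(lo, 6), ", ",
         signif(hi, 6), "]")
  (phi_total - lo) / (hi - lo)
}

#' Reduced (temperature-scaled) coexistence curve
#'
#' Maps each binodal point of a phase diagram to scaled coordinates
#' \eqn{(\phi/\phi_{crit},\, T_{rel}/T_{crit})} with the relative
#' temperature \eqn{T_{rel} \equiv -1/\epsilon^*}. Curves for different
#' well ranges nearly collapse near the apex in these coordinates.
#'
#' @param diagram An `sw_phase_diagram`.
#' @return A data.frame with `branch` (`"dilute"`/`"concentrated"`),
#'   `phi_scaled`, `T_scaled`; the critical point maps to (1, 1).
#' @export
reduced_coexistence <- function(diagram) {
  stopifnot(inherits(diagram, "sw_phase_diagram"))
  pts <- diagram$points
  if (any(pts$eps_star >= 0))
    stop("reduced temperature undefined for eps_star >= 0")
  crit <- diagram$critical
  T_crit <- -1 / crit$eps_crit
  T_rel <- -1 / pts$eps_star
  data.frame(branch = rep(c("dilute", "concentrated"),
                          each = nrow(pts)),
             phi_scaled = c(pts$phi_dil_eq, pts$phi_conc_eq) / crit$phi_crit,
             T_scaled = rep(T_rel / T_crit, 2))
}
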