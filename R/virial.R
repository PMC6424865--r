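# Osmotic virial coefficients of the single-species square-well fluid.
# Convention: B2, B3 are the McMillan-Mayer osmotic virial coefficients in
# number-density units (volume / molecule and volume^2 / molecule^2); the
# activity module owns the factors 2 and 3/2 that relate them to the
# ln(gamma) expansion.

b2_hard_sphere <- function(sigma = 1) 2 * pi / 3 * sigma^3

#' Second osmotic virial coefficient of a square-well fluid
#'
#' Closed form \eqn{B_2 = (2\pi/3)\sigma^3 [1 - (L^3 - 1)(e^{-\epsilon^*} - 1)]}.
#' Reduces to the hard-sphere value \eqn{(2\pi/3)\sigma^3} when
#' `eps_star = 0` or `L = 1`.
#'
#' @param params An [sw_interaction()].
#' @param sigma Hard-core diameter (reduced units), default 1.
#' @return \eqn{B_2} in volume/molecule.
#' @export
b2_square_well <- function(params, sigma = 1) {
  stopifnot(inherits(params, "sw_interaction"), sigma > 0)
  f <- expm1(-params$eps_star)
  b2_hard_sphere(sigma) * (1 - (params$L^3 - 1) * f)
}

#' Third osmotic virial coefficient of a square-well fluid
#'
#' Exact closed form, a cubic polynomial in the well Mayer factor
#' \eqn{f = e^{-\epsilon^*} - 1} whose coefficients are piecewise polynomials
#' in `L` (the geometry of triple sphere overlaps changes at `L = 2`). The
#' two branches are continuous at `L = 2`, and the whole expression is
#' validated in the test suite against the seeded Monte-Carlo cluster
#' integral of [b3_numeric()]. At `eps_star = 0` or `L = 1` it reduces to the
#' hard-sphere value \eqn{(5/8) B_2^2}.
#'
#' @inheritParams b2_square_well
#' @return \eqn{B_3} in volume^2/molecule^2.
#' @export
b3_square_well <- function(params, sigma = 1) {
  stopifnot(inherits(params, "sw_interaction"), sigma > 0)
  L <- params$L
  f <- expm1(-params$eps_star)
  if (L <= 2) {
    c1 <- (L^6 - 18 * L^4 + 32 * L^3 - 15) / 8
    c2 <- (2 * L^6 - 36 * L^4 + 32 * L^3 + 18 * L^2 - 16) / 8
    c3 <- (6 * L^6 - 18 * L^4 + 18 * L^2 - 6) / 8
  } else {
    # beyond L = 2 the unit spheres around two well-partners always overlap,
    # so the linear-in-f geometry saturates
    c1 <- 17 / 8
    c2 <- (-32 * L^3 + 18 * L^2 + 48) / 8
    c3 <- (5 * L^6 - 32 * L^3 + 18 * L^2 + 26) / 8
  }
  b2_hard_sphere(sigma)^2 * (5 / 8 - f * c1 - f^2 * c2 - f^3 * c3)
}

#' Steric-subtracted ("soft") virial components
#'
#' The soft components are the full square-well virials minus their
#' hard-sphere (`eps_star = 0`) parts:
#' \eqn{B_{2,soft} = B_2 - B_2^{HS}}, \eqn{B_{3,soft} = B_3 - B_3^{HS}}.
#' They vanish identically at `eps_star = 0` and are negative for attraction.
#'
#' @inheritParams b2_square_well
#' @return A list with components `B2_soft` and `B3_soft`.
#' @export
soft_components <- function(params, sigma = 1) {
  hs <- sw_interaction(params$L, 0)
  list(B2_soft = b2_square_well(params, sigma) - b2_square_well(hs, sigma),
       B3_soft = b3_square_well(params, sigma) - b3_square_well(hs, sigma))
}

#' Numerical B2 by radial quadrature
#'
#' Independent oracle for [b2_square_well()]:
#' \eqn{B_2 = -2\pi \int_0^\infty (e^{-U(r)} - 1) r^2 dr}, evaluated with
#' adaptive quadrature on each branch of the potential.
#'
#' @inheritParams b2_square_well
#' @param rel_tol Relative quadrature tolerance.
#' @return \eqn{B_2} in volume/molecule.
#' @export
b2_numeric <- function(params, sigma = 1, rel_tol = 1e-10) {
  stopifnot(inherits(params, "sw_interaction"), sigma > 0)
  f_core <- stats::integrate(function(r) -2 * pi * (-1) * r^2,
                             0, sigma, rel.tol = rel_tol)$value
  if (params$L > 1) {
    fw <- expm1(-params$eps_star)
    f_well <- stats::integrate(function(r) -2 * pi * fw * r^2,
                               sigma, params$L * sigma, rel.tol = rel_tol)$value
  } else {
    f_well <- 0
  }
  f_core + f_well
}

#' Numerical B3 by Monte-Carlo cluster integration
#'
#' Independent oracle for [b3_square_well()]: the irreducible three-body
#' cluster integral
#' \eqn{B_3 = -(1/3) \int\int f_{12} f_{13} f_{23} \, d r_2 \, d r_3},
#' estimated by seeded uniform sampling of the two satellite positions in
#' the ball of radius \eqn{L\sigma} around particle 1 (outside of which
#' \eqn{f_{12} f_{13} = 0}).
#'
#' @inheritParams b2_square_well
#' @param n_samples Number of Monte-Carlo samples (`>= 1e5` recommended;
#'   fewer triggers a warning flag in the result).
#' @param seed Integer RNG seed (recorded in the result).
#' @param chunk Samples per vectorized block (memory control).
#' @return A list with `estimate`, `se` (standard error), `n_samples`,
#'   `seed` and logical `low_sample_warning`.
#' @export
b3_numeric <- function(params, sigma = 1, n_samples = 1e6, seed = 1,
                       chunk = 1e6) {
  stopifnot(inherits(params, "sw_interaction"), sigma > 0, n_samples >= 1)
  L <- params$L
  fw <- expm1(-params$eps_star)
  R <- L * sigma
  V <- 4 * pi / 3 * R^3
  mayer <- function(d) ifelse(d < sigma, -1, ifelse(d < L * sigma, fw, 0))
  sample_ball <- function(n) {
    u <- stats::runif(n)^(1 / 3) * R
    ct <- stats::runif(n, -1, 1)
    ph <- stats::runif(n, 0, 2 * pi)
    st <- sqrt(pmax(0, 1 - ct^2))
    cbind(u * st * cos(ph), u * st * sin(ph), u * ct)
  }
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  n_left <- n_samples
  s <- 0; s2 <- 0; n_done <- 0
  while (n_left > 0) {
    n <- min(chunk, n_left)
    r2 <- sample_ball(n)
    r3 <- sample_ball(n)
    w <- mayer(sqrt(rowSums(r2^2))) * mayer(sqrt(rowSums(r3^2))) *
      mayer(sqrt(rowSums((r2 - r3)^2)))
    s <- s + sum(w)
    s2 <- s2 + sum(w^2)
    n_done <- n_done + n
    n_left <- n_left - n
  }
  m <- s / n_done
  v <- (s2 / n_done - m^2) * n_done / (n_done - 1)
  list(estimate = -V^2 / 3 * m,
       se = V^2 / 3 * sqrt(v / n_done),
       n_samples = n_done, seed = seed,
       low_sample_warning = n_done < 1e5)
}

#' Virial coefficient table over a parameter grid
#'
#' Tabulates analytic and (optionally) numerical virial coefficients over
#' the cartesian grid of `L_values` and `eps_values`; suitable for CSV
#' export.
#'
#' @param L_values,eps_values Numeric vectors of well ranges and depths.
#' @param sigma Hard-core diameter.
#' @param check If `TRUE`, add numerical-oracle columns `B2_numeric`,
#'   `B3_numeric`, `B3_numeric_se`.
#' @param n_samples,seed Monte-Carlo settings for the B3 oracle.
#' @return A data.frame with columns `L`, `eps_star`, `B2`, `B3`, `B2_soft`,
#'   `B3_soft` (plus oracle columns when `check = TRUE`).
#' @export
virial_table <- function(L_values, eps_values, sigma = 1, check = FALSE,
                         n_samples = 1e6, seed = 1) {
  grid <- expand.grid(L = L_values, eps_star = eps_values,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- sw_interaction(grid$L[i], grid$eps_star[i])
    soft <- soft_components(p, sigma)
    row <- data.frame(L = p$L, eps_star = p$eps_star,
                      B2 = b2_square_well(p, sigma),
                      B3 = b3_square_well(p, sigma),
                      B2_soft = soft$B2_soft, B3_soft = soft$B3_soft)
    if (check) {
      mc <- b3_numeric(p, sigma, n_samples = n_samples, seed = seed + i)
      row$B2_numeric <- b2_numeric(p, sigma)
      row$B3_numeric <- mc$estimate
      row$B3_numeric_se <- mc$se
    }
    row
  })
  do.call(rbind, rows)
}
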