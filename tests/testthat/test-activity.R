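test_that("SPT ln gamma matches Gibbs-Duhem integration of Z and slope 8", {
  # independent oracle: ln gamma = (Z - 1) + integral of (Z - 1)/phi
  lngamma_gd <- function(phi) {
    zm1 <- function(t) (1 + t + t^2) / (1 - t)^3 - 1
    zm1(phi) + stats::integrate(function(t) zm1(t) / t, 0, phi,
                                rel.tol = 1e-12)$value
  }
  for (phi in c(0.1, 0.3, 0.5))
    expect_equal(lngamma_spt_hs(phi), lngamma_gd(phi), tolerance = 1e-8)
  expect_identical(lngamma_spt_hs(0), 0)
  h <- 1e-7
  expect_equal(lngamma_spt_hs(h) / h, 8, tolerance = 1e-5)
  expect_error(lngamma_spt_hs(1), "\\[0, 1\\)")
})

test_that("SPT ln gamma is convex increasing on [0, 0.5]", {
  phi <- seq(0, 0.5, by = 0.01)
  y <- lngamma_spt_hs(phi)
  expect_true(all(diff(y) > 0))
  expect_true(all(diff(diff(y)) > 0))
  # analytic derivative consistent with finite differences
  expect_equal(sqwell:::dlngamma_spt_dphi(0.3),
               (lngamma_spt_hs(0.3 + 1e-6) - lngamma_spt_hs(0.3 - 1e-6)) / 2e-6,
               tolerance = 1e-6)
})

test_that("Carnahan-Starling alternative has the same structure", {
  expect_identical(lngamma_cs_hs(0), 0)
  expect_equal(lngamma_cs_hs(1e-7) / 1e-7, 8, tolerance = 1e-5)
  # SPT and CS agree closely at moderate occupancy but are distinct
  expect_equal(lngamma_cs_hs(0.2), lngamma_spt_hs(0.2), tolerance = 0.01)
  expect_false(identical(lngamma_cs_hs(0.4), lngamma_spt_hs(0.4)))
})

test_that("soft term composes the soft virials with the 2, 3/2 factors", {
  p <- sw_interaction(1.25, -1)
  expect_equal(lngamma_soft(seq(0, 0.4, 0.1), sw_interaction(1.25, 0)),
               rep(0, 5))
  soft <- soft_components(p)
  rho <- 6 * 0.2 / pi
  expect_equal(lngamma_soft(0.2, p),
               2 * soft$B2_soft * rho + 1.5 * soft$B3_soft * rho^2)
  # leading-order limit
  expect_equal(lngamma_soft(1e-8, p) / 1e-8, 2 * soft$B2_soft * 6 / pi,
               tolerance = 1e-6)
})

test_that("Kihara+ reduces to SPT at eps = 0 and orders by well depth", {
  phi <- seq(0.01, 0.4, by = 0.01)
  expect_identical(lngamma_kihara_plus(phi, sw_interaction(1.25, 0)),
                   lngamma_spt_hs(phi))
  # more attraction -> smaller ln gamma at fixed phi
  vals <- sapply(c(0, -0.5, -1.0, -1.5), function(e)
    lngamma_kihara_plus(0.2, sw_interaction(1.25, e)))
  expect_true(all(diff(vals) < 0))
  # strong attraction: negative at small phi; the hard core dominates at
  # high occupancy and eventually turns ln gamma positive
  y <- lngamma_kihara_plus(c(0.05, 0.55), sw_interaction(1.25, -1.5))
  expect_lt(y[1], 0)
  expect_gt(y[2], 0)
  # analytic derivative of the full model
  p <- sw_interaction(1.25, -1)
  num <- (lngamma_kihara_plus(0.2 + 1e-6, p) -
            lngamma_kihara_plus(0.2 - 1e-6, p)) / 2e-6
  expect_equal(dlngamma_kihara_plus_dphi(0.2, p), num, tolerance = 1e-6)
})

test_that("quartic fit recovers exact polynomial data and fits SPT well", {
  phi <- seq(0.01, 0.4, by = 0.01)
  Q_true <- c(8, -3, 12, 5)
  y <- Q_true[1] * phi + Q_true[2] * phi^2 + Q_true[3] * phi^3 +
    Q_true[4] * phi^4
  fit <- fit_quartic(activity_curve(phi, y))
  expect_equal(unname(fit$Q), Q_true, tolerance = 1e-9)
  expect_lt(fit$fit_residual, 1e-12)
  # all-zero curve
  fit0 <- fit_quartic(data.frame(phi = phi, lngamma = 0 * phi))
  expect_equal(unname(fit0$Q), rep(0, 4))
  # quartic adequacy for the SPT curve
  spt_fit <- fit_quartic(activity_curve(phi, lngamma_spt_hs(phi),
                                        source = "spt"))
  expect_lt(spt_fit$fit_residual, 1e-2)
  # round trip within reported residual
  back <- eval_quartic(spt_fit, phi)
  expect_lt(max(abs(back - lngamma_spt_hs(phi))), 10 * spt_fit$fit_residual)
  expect_error(fit_quartic(data.frame(phi = phi[1:5], lngamma = y[1:5])),
               "at least 8")
})

test_that("activity curve validation rejects malformed grids", {
  expect_error(activity_curve(c(0.2, 0.1), c(1, 2)), "increasing")
  expect_error(activity_curve(c(0.1, 0.2), c(1, Inf)), "finite")
  expect_error(activity_curve(c(0, 0.2), c(0, 1)), "\\(0, 1\\)")
})

test_that("quartic derivative and integral terms obey calculus identities", {
  Q <- c(8, 0, 0, 0)
  expect_equal(as.numeric(phi_dlngamma_dphi(Q, 0.1)), 0.8)
  expect_identical(as.numeric(phi_dlngamma_dphi(Q, 0)), 0)
  expect_equal(suppressWarnings(as.numeric(integral_term(c(2, 0, 0, 0), 0.5))),
               0.25)
  expect_identical(as.numeric(integral_term(Q, 0)), 0)
  Q2 <- c(8, -3, 12, 5)
  phi <- seq(0.05, 0.35, by = 0.05)
  # phi * d/dphi of the quartic
  d_num <- (eval_quartic(Q2, phi + 1e-7) - eval_quartic(Q2, phi - 1e-7)) / 2e-7
  expect_equal(as.numeric(phi_dlngamma_dphi(Q2, phi)), phi * d_num,
               tolerance = 1e-6)
  # fundamental theorem: d(integral_term)/dphi = phi dlngamma/dphi
  i_num <- (integral_term(Q2, phi + 1e-7) - integral_term(Q2, phi - 1e-7)) / 2e-7
  expect_equal(as.numeric(i_num), as.numeric(phi_dlngamma_dphi(Q2, phi)),
               tolerance = 1e-6)
})

test_that("evaluation outside the fit domain warns and flags", {
  fit <- fit_quartic(kihara_plus_curve(sw_interaction(1.25, -1)))
  expect_warning(out <- eval_quartic(fit, c(0.2, 0.5)), "outside")
  expect_identical(attr(out, "extrapolated"), c(FALSE, TRUE))
})
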