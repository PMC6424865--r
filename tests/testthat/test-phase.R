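model <- kihara_activity_model(1.25)
crit <- critical_point(model)

test_that("no spinodal for pure repulsion, double root at criticality", {
  expect_null(spinodal(model, 0))
  expect_null(spinodal(model, -0.5))
  # slightly above the critical depth: stable; slightly below: two roots
  expect_null(spinodal(model, crit$eps_crit + 0.01))
  sp <- spinodal(model, crit$eps_crit - 0.01)
  expect_false(is.null(sp))
  expect_lt(sp$phi_upper_star - sp$phi_lower_star, 0.12)
  expect_gt(sp$phi_upper_star, sp$phi_lower_star)
  # both roots close to phi_crit
  expect_equal(sp$phi_lower_star, crit$phi_crit, tolerance = 0.3)
})

test_that("spinodal roots agree with a dense-grid sign-change oracle", {
  sp <- spinodal(model, -1.4)
  Q <- model$quartic_fun(-1.4)
  grid <- seq(0.001, 0.6, by = 1e-4)
  v <- sqwell:::q_dPi(Q, grid)
  idx <- which(v[-1] * v[-length(v)] < 0)
  expect_length(idx, 2)
  brute <- grid[idx]
  expect_equal(sp$phi_lower_star, brute[1], tolerance = 1e-3)
  expect_equal(sp$phi_upper_star, brute[2], tolerance = 1e-3)
})

test_that("binodal satisfies equal pressure and chemical potential to 1e-8", {
  for (eps in crit$eps_crit - c(0.07, 0.2, 0.4)) {
    bn <- binodal(model, eps)
    th <- sqwell:::thermo_funs(model, eps, bn$method)
    expect_lt(abs(th$Pi(bn$phi_dil_eq) - th$Pi(bn$phi_conc_eq)), 1e-8)
    expect_lt(abs(th$mu(bn$phi_dil_eq) - th$mu(bn$phi_conc_eq)), 1e-8)
    # nesting: spinodal strictly inside the binodal
    sp <- spinodal(model, eps, method = bn$method)
    expect_lt(bn$phi_dil_eq, sp$phi_lower_star)
    expect_gt(bn$phi_conc_eq, sp$phi_upper_star)
  }
  expect_null(binodal(model, -0.5))
})

test_that("binodal matches the Maxwell equal-area construction to 1e-3", {
  for (eps in crit$eps_crit - c(0.1, 0.3)) {
    bn <- binodal(model, eps, method = "quartic")
    mx <- binodal_maxwell(model, eps)
    expect_equal(bn$phi_dil_eq, mx$phi_dil_eq, tolerance = 1e-3)
    expect_equal(bn$phi_conc_eq, mx$phi_conc_eq, tolerance = 1e-3)
  }
})

test_that("binodal branches converge to the critical point from below", {
  bn <- binodal(model, crit$eps_crit - 0.005)
  expect_lt(abs(bn$phi_dil_eq - crit$phi_crit), 0.05)
  expect_lt(abs(bn$phi_conc_eq - crit$phi_crit), 0.05)
})

test_that("reference critical points are reproduced by the quartic pipeline", {
  expect_equal(crit$phi_crit, 0.13, tolerance = 0.015 / 0.13)
  expect_equal(crit$eps_crit, -1.33, tolerance = 0.03 / 1.33)
  crit15 <- critical_point(kihara_activity_model(1.5))
  expect_equal(crit15$phi_crit, 0.12, tolerance = 0.015 / 0.12)
  expect_equal(crit15$eps_crit, -0.80, tolerance = 0.03 / 0.80)
  # longer range separates at weaker attraction
  expect_gt(crit15$eps_crit, crit$eps_crit)
})

test_that("critical point search fails cleanly outside its box", {
  expect_error(critical_point(model, eps_box = c(-0.5, -0.3)),
               "no critical point")
})

test_that("phase diagram respects nesting and apex consistency", {
  pd <- phase_diagram(model)
  expect_s3_class(pd, "sw_phase_diagram")
  expect_gt(nrow(pd$points), 20)
  expect_length(pd$failures, 0)
  with(pd$points, {
    expect_true(all(phi_dil_eq <= phi_lower_star))
    expect_true(all(phi_lower_star < phi_upper_star))
    expect_true(all(phi_upper_star <= phi_conc_eq))
  })
  expect_true(all(diff(pd$points$eps_star) > 0))
  # apexes of the fitted curves sit near the critical point
  expect_equal(fit_apex(pd$binodal_fit)$phi, pd$critical$phi_crit,
               tolerance = 0.01 / pd$critical$phi_crit)
  expect_equal(fit_apex(pd$spinodal_fit)$phi, pd$critical$phi_crit,
               tolerance = 0.01 / pd$critical$phi_crit)
})

test_that("osmotic pressure is monotone for all eps above critical", {
  phi <- seq(0.001, 0.6, by = 0.001)
  for (eps in crit$eps_crit + c(0.01, 0.1, 0.4, 0.8)) {
    Q <- model$quartic_fun(eps)
    expect_true(all(sqwell:::q_dPi(Q, phi) > 0))
  }
})

test_that("lever rule interpolates between the coexisting phases", {
  bn <- binodal(model, -1.5)
  expect_equal(lever_rule(bn$phi_dil_eq, bn), 0)
  expect_equal(lever_rule(bn$phi_conc_eq, bn), 1)
  mid <- (bn$phi_dil_eq + bn$phi_conc_eq) / 2
  expect_equal(lever_rule(mid, bn), 0.5)
  expect_error(lever_rule(bn$phi_dil_eq - 0.01, bn), "outside")
})

test_that("reduced coexistence curves scale the critical point to (1, 1)", {
  pd <- phase_diagram(model,
                      eps_grid = seq(crit$eps_crit - 0.3,
                                     crit$eps_crit - 0.02, by = 0.02))
  rc <- reduced_coexistence(pd)
  expect_true(all(rc$T_scaled <= 1))
  # approaching criticality both branches approach phi_scaled = 1
  near <- rc[abs(rc$T_scaled - max(rc$T_scaled)) < 1e-12, ]
  expect_equal(mean(near$phi_scaled), 1, tolerance = 0.2)
  # collapse near the apex across well ranges
  m15 <- kihara_activity_model(1.5)
  c15 <- critical_point(m15)
  pd15 <- phase_diagram(m15,
                        eps_grid = seq(c15$eps_crit - 0.3,
                                       c15$eps_crit - 0.02, by = 0.02))
  rc15 <- reduced_coexistence(pd15)
  t_at <- function(rc, s) {
    d <- rc[rc$branch == "dilute", ]
    stats::approx(d$T_scaled, d$phi_scaled, xout = s)$y
  }
  for (s in c(0.97, 0.94))
    expect_equal(t_at(rc, s), t_at(rc15, s), tolerance = 0.25)
})

test_that("table-backed models support the same constructions", {
  eps_tab <- seq(-1.6, -1.1, by = 0.1)
  Q_tab <- t(vapply(eps_tab, function(e) model$quartic_fun(e)$Q, numeric(4)))
  tm <- table_activity_model(eps_tab, Q_tab, L = 1.25)
  ct <- critical_point(tm, eps_box = c(-1.6, -1.1))
  expect_equal(ct$phi_crit, crit$phi_crit, tolerance = 1e-3)
  expect_equal(ct$eps_crit, crit$eps_crit, tolerance = 1e-3)
  expect_error(thermo <- binodal(tm, -1.5, method = "exact"),
               "not available")
})
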