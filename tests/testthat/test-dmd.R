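p_att <- sw_interaction(1.25, -1.0)
p_hs <- sw_interaction(1.25, 0)
box <- 20

# brute-force oracle: first boundary crossing along the free-flight path
scan_first_crossing <- function(r_rel, v_rel, L, bonded, t_max = 8,
                                dt = 1e-6) {
  t <- seq(0, t_max, by = dt)
  d <- sqrt((r_rel[1] + v_rel[1] * t)^2 + (r_rel[2] + v_rel[2] * t)^2 +
              (r_rel[3] + v_rel[3] * t)^2)
  if (bonded) {
    hit_core <- which(d < 1)[1]
    hit_out <- which(d >= L)[1]
    hits <- c(core_collision = hit_core, well_exit_attempt = hit_out)
  } else {
    hits <- c(well_entry = which(d < L)[1])
  }
  hits <- hits[!is.na(hits)]
  if (length(hits) == 0) return(list(time = Inf, type = "none"))
  k <- which.min(hits)
  list(time = t[hits[k]], type = names(hits)[k])
}

test_that("pair event prediction matches a dense trajectory scan", {
  # head-on approach from distance 2 at unit closing speed, wide well:
  # core collision when the gap of 1 sigma closes
  ev <- next_event(c(2, 0, 0), c(-1, 0, 0), box,
                   sw_interaction(3, -1), bonded = TRUE)
  expect_equal(ev$time, 1, tolerance = 1e-12)
  expect_equal(ev$type, "core_collision")
  # receding pair outside the well: no event
  ev2 <- next_event(c(2, 0, 0), c(1, 0.2, 0), box, p_att, bonded = FALSE)
  expect_equal(ev2$type, "none")
  expect_identical(ev2$time, Inf)
  # randomized configurations against the brute-force oracle
  set.seed(42)
  n_checked <- 0
  for (i in 1:40) {
    bonded <- runif(1) < 0.5
    d0 <- if (bonded) runif(1, 1.001, 1.249) else runif(1, 1.3, 3)
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    r <- d0 * dir
    v <- rnorm(3)
    ev <- next_event(r, v, box, p_att, bonded = bonded)
    oracle <- scan_first_crossing(r, v, 1.25, bonded)
    if (is.finite(oracle$time)) {
      expect_lt(abs(ev$time - oracle$time), 2e-6)  # oracle grid is 1e-6
      expect_equal(ev$type, oracle$type)
      n_checked <- n_checked + 1
    } else {
      expect_identical(ev$time, Inf)
    }
  }
  expect_gt(n_checked, 10)
  expect_error(next_event(c(0.5, 0, 0), c(1, 0, 0), box, p_att, FALSE),
               "overlapping")
})

test_that("event resolution conserves momentum and energy in every branch", {
  u <- function(v) v / sqrt(sum(v^2))
  check_branch <- function(r_i, r_j, v_i, v_j, bonded, type, p = p_att) {
    before_p <- v_i + v_j
    before_ke <- 0.5 * sum(v_i^2) + 0.5 * sum(v_j^2)
    u_before <- if (bonded) p$eps_star else 0
    out <- resolve_event(r_i, r_j, v_i, v_j, box, p, bonded, type)
    after_ke <- 0.5 * sum(out$v_i^2) + 0.5 * sum(out$v_j^2)
    u_after <- if (out$bonded) p$eps_star else 0
    expect_equal(out$v_i + out$v_j, before_p, tolerance = 1e-12)
    expect_equal(after_ke + u_after, before_ke + u_before,
                 tolerance = 1e-12)
    out
  }
  # core collision reverses the normal relative velocity
  out <- check_branch(c(0, 0, 0), c(1, 0, 0), c(1, 0.3, 0), c(-1, 0, 0),
                      bonded = TRUE, type = "core_collision")
  expect_true(out$bonded)
  expect_equal(out$v_i, c(-1, 0.3, 0))
  # well entry: capture, kinetic energy increases by |eps|
  out <- check_branch(c(0, 0, 0), c(1.25, 0, 0), c(0.5, 0, 0), c(-0.5, 0, 0),
                      bonded = FALSE, type = "well_entry")
  expect_true(out$bonded)
  # slow exit attempt: bounce, pair stays bonded
  out <- check_branch(c(0, 0, 0), c(1.25, 0, 0), c(-0.5, 0, 0), c(0.5, 0, 0),
                      bonded = TRUE, type = "well_exit_attempt")
  expect_true(out$bonded)
  expect_false(out$escaped)
  # fast exit attempt: escape with reduced normal speed
  out <- check_branch(c(0, 0, 0), c(1.25, 0, 0), c(-2, 0, 0), c(2, 0, 0),
                      bonded = TRUE, type = "well_exit_attempt")
  expect_false(out$bonded)
  expect_true(out$escaped)
  # inconsistent bookkeeping is rejected
  expect_error(resolve_event(c(0, 0, 0), c(1.25, 0, 0), c(1, 0, 0),
                             c(-1, 0, 0), box, p_att, TRUE, "well_entry"),
               "inconsistent")
})

test_that("eps = 0 well events are no-ops: dynamics is pure hard spheres", {
  ev <- next_event(c(1.1, 0, 0), c(-1, 0, 0), box, p_hs, bonded = FALSE)
  expect_equal(ev$type, "core_collision")
  expect_equal(ev$time, 0.1, tolerance = 1e-12)
  sim <- run_nvt(N = 64, phi = 0.1, params = p_hs, t_equil = 2,
                 t_sample = 10, sample_interval = 5, seed = 3)
  expect_equal(sim$n_entry + sim$n_exit_escape + sim$n_exit_bounce, 0)
})

test_that("runs are deterministic given the seed", {
  a <- run_nvt(N = 64, phi = 0.15, params = p_att, t_equil = 2, t_sample = 6,
               sample_interval = 2, seed = 99)
  b <- run_nvt(N = 64, phi = 0.15, params = p_att, t_equil = 2, t_sample = 6,
               sample_interval = 2, seed = 99)
  expect_identical(a$snapshots[[3]]$positions, b$snapshots[[3]]$positions)
  expect_identical(a$n_events, b$n_events)
  c <- run_nvt(N = 64, phi = 0.15, params = p_att, t_equil = 2, t_sample = 6,
               sample_interval = 2, seed = 100)
  expect_false(identical(a$snapshots[[3]]$positions,
                         c$snapshots[[3]]$positions))
})

test_that("microcanonical runs conserve energy and momentum", {
  sim <- run_nvt(N = 128, phi = 0.25, params = p_att, t_equil = 0,
                 t_sample = 15, sample_interval = 5, thermostat = FALSE,
                 seed = 7)
  expect_gt(sim$n_events, 1e4)
  expect_lt(sim$max_energy_drift, 1e-8)
  expect_lt(sim$net_momentum, 1e-9)
})

test_that("no hard-core overlap ever appears in snapshots", {
  for (sd in 1:2) {
    sim <- run_nvt(N = 128, phi = 0.3, params = p_att, t_equil = 5,
                   t_sample = 20, sample_interval = 2, seed = sd)
    expect_gte(sim$min_snapshot_distance, 1 - 1e-12)
  }
})

test_that("hard-sphere pressure matches the SPT equation of state", {
  sim <- run_nvt(N = 256, phi = 0.2, params = p_hs, t_equil = 10,
                 t_sample = 60, sample_interval = 2, seed = 11)
  expect_equal(sim$Z_virial, (1 + 0.2 + 0.04) / 0.8^3,
               tolerance = 0.02)
})

test_that("Widom estimates reproduce SPT at eps = 0 and the ideal limit", {
  sim <- run_nvt(N = 256, phi = 0.1, params = p_hs, t_equil = 10,
                 t_sample = 50, sample_interval = 2, seed = 13)
  w <- widom_lngamma(sim, n_insertions = 5e3, seed = 13)
  expect_lt(abs(w$lngamma - lngamma_spt_hs(0.1)),
            max(3 * w$standard_error, 0.02))
  # very dilute: ln gamma ~ 0
  sim0 <- run_nvt(N = 64, phi = 0.005, params = p_hs, t_equil = 2,
                  t_sample = 20, sample_interval = 2, seed = 17)
  w0 <- widom_lngamma(sim0, n_insertions = 2e3, seed = 17)
  expect_lt(abs(w0$lngamma), 0.05)
})

test_that("low-density Widom slope is consistent with the virial module", {
  # ln gamma / phi -> 2 B2 rho / phi = 2 B2 (6 / pi) as phi -> 0
  sim <- run_nvt(N = 128, phi = 0.02, params = p_att, t_equil = 5,
                 t_sample = 80, sample_interval = 2, seed = 19)
  w <- widom_lngamma(sim, n_insertions = 1e4, seed = 19)
  slope_virial <- 2 * b2_square_well(p_att) * 6 / pi
  expect_lt(abs(w$lngamma / 0.02 - slope_virial),
            max(3 * w$standard_error / 0.02, 0.4))
})

test_that("infeasible initial packings are rejected", {
  expect_error(run_nvt(N = 256, phi = 0.8, params = p_hs, seed = 1),
               "cannot place")
})
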