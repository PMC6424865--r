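# R surface of the event-driven square-well simulator (src/dmd.cpp) and the
# Widom-insertion estimator of ln gamma.

#' Run an NVT square-well discrete molecular dynamics simulation
#'
#' Event-driven dynamics of `N` identical square-well spheres in a cubic
#' periodic box at volume fraction `phi`. Particles start on a face-centred
#' cubic lattice with Maxwell-Boltzmann velocities (zero net momentum);
#' an Andersen-style thermostat (full velocity redraw at fixed reduced-time
#' intervals) holds the reduced temperature during equilibration and
#' sampling. With `thermostat = FALSE` the run is microcanonical and tracks
#' the total-energy drift (conservation audit). Fully reproducible from
#' `seed`.
#'
#' @param N Number of particles (`>= 64` for production use).
#' @param phi Volume fraction, feasible for lattice initialization
#'   (roughly `<= 0.45`).
#' @param params An [sw_interaction()].
#' @param temperature Reduced temperature (default 1; the well depth already
#'   carries kT, so this stays at 1 in normal use).
#' @param t_equil,t_sample Equilibration and sampling durations (reduced
#'   time).
#' @param sample_interval Time between recorded snapshots.
#' @param thermostat Logical; `FALSE` gives a microcanonical conservation
#'   audit.
#' @param thermostat_interval Time between velocity redraws.
#' @param seed Integer seed.
#' @return An object of class `sw_simulation`: list with `snapshots` (each
#'   with `positions`, `velocities`, `time`), `box_length`, the run
#'   parameters, the virial compressibility factor `Z_virial`, event counts,
#'   `max_energy_drift`, `min_snapshot_distance` and `net_momentum`.
#' @export
run_nvt <- function(N = 256, phi, params, temperature = 1,
                    t_equil = 50, t_sample = 200, sample_interval = 2,
                    thermostat = TRUE, thermostat_interval = 0.5,
                    seed = 1) {
  stopifnot(inherits(params, "sw_interaction"))
  res <- .dmd_run_cpp(N = as.integer(N), phi = phi, L = params$L,
                      eps = params$eps_star, Tstar = temperature,
                      t_equil = t_equil, t_sample = t_sample,
                      sample_interval = sample_interval,
                      thermostat_interval = thermostat_interval,
                      thermostat = thermostat,
                      sync_interval = 0.1, seed = as.integer(seed))
  class(res) <- "sw_simulation"
  res
}

#' @export
print.sw_simulation <- function(x, ...) {
  cat(sprintf("Square-well DMD run: N = %d, phi = %.3f, L = %g, eps* = %g\n",
              x$N, x$phi, x$L, x$eps_star))
  cat(sprintf("  %d snapshots over t = %.1f; %.0f events (Z = %.4f)\n",
              length(x$snapshots), x$t_sampled, x$n_events,
              x$Z_virial))
  invisible(x)
}

#' Widom-insertion estimate of ln gamma
#'
#' Estimates the excess chemical potential (in kT) of the simulated fluid by
#' ghost-particle insertion: for each snapshot, `n_insertions` random
#' positions are tried; an insertion overlapping a hard core contributes a
#' Boltzmann factor of exactly 0, otherwise it contributes
#' \eqn{e^{-\epsilon^* n_{well}}} with \eqn{n_{well}} the number of host
#' particles within the well range. Then
#' \eqn{\ln\gamma = -\ln \langle e^{-\Delta U} \rangle}; the standard error
#' comes from block averaging over snapshots.
#'
#' @param sim An `sw_simulation` from [run_nvt()] (at least 20 decorrelated
#'   snapshots recommended).
#' @param n_insertions Insertions per snapshot.
#' @param seed Integer seed for insertion positions.
#' @return An object of class `sw_widom`: list with `lngamma`,
#'   `standard_error`, `n_insertions`, `n_samples` (snapshots), `phi`,
#'   `frac_overlap`.
#' @export
widom_lngamma <- function(sim, n_insertions = 1e4, seed = 1) {
  stopifnot(inherits(sim, "sw_simulation"))
  if (length(sim$snapshots) < 2)
    stop("need at least 2 snapshots for a block standard error")
  w <- .widom_cpp(sim$snapshots, box = sim$box_length, L = sim$L,
                  eps = sim$eps_star, n_insertions = as.integer(n_insertions),
                  seed = as.integer(seed))
  m <- mean(w$mean_weight)
  if (m <= 0)
    stop("all insertions overlapped a hard core: phi too high or too few ",
         "insertions")
  se_m <- stats::sd(w$mean_weight) / sqrt(length(w$mean_weight))
  structure(list(lngamma = -log(m),
                 standard_error = se_m / m,
                 n_insertions = w$n_insertions,
                 n_samples = length(w$mean_weight),
                 phi = sim$phi,
                 frac_overlap = mean(w$frac_overlap)),
            class = "sw_widom")
}

#' @export
print.sw_widom <- function(x, ...) {
  cat(sprintf("Widom estimate: ln(gamma) = %.4f +/- %.4f (phi = %.3f, %d x %d insertions)\n",
              x$lngamma, x$standard_error, x$phi, x$n_samples,
              x$n_insertions))
  invisible(x)
}

#' Simulated ln gamma at a state point
#'
#' One-stop wrapper: runs [run_nvt()] and [widom_lngamma()].
#'
#' @inheritParams run_nvt
#' @inheritParams widom_lngamma
#' @return An `sw_widom` estimate.
#' @export
lngamma_simulation <- function(phi, params, N = 256, t_equil = 50,
                               t_sample = 200, sample_interval = 2,
                               n_insertions = 1e4, seed = 1) {
  sim <- run_nvt(N = N, phi = phi, params = params, t_equil = t_equil,
                 t_sample = t_sample, sample_interval = sample_interval,
                 seed = seed)
  widom_lngamma(sim, n_insertions = n_insertions, seed = seed + 1L)
}

#' Next boundary-crossing event of a particle pair
#'
#' Earliest future time at which the pair's minimum-image distance crosses
#' the hard core (`sigma = 1`) or the outer well boundary (`L * sigma`),
#' given linear free flight; `Inf` with type `"none"` if the relative motion
#' never crosses either boundary.
#'
#' @param r_rel,v_rel Relative position and velocity of the pair (length-3).
#' @param box_length Periodic box edge.
#' @param params An [sw_interaction()].
#' @param bonded Is the pair currently inside each other's well?
#' @return List with `time` and `type` (`"core_collision"`, `"well_entry"`,
#'   `"well_exit_attempt"` or `"none"`).
#' @export
next_event <- function(r_rel, v_rel, box_length, params, bonded = FALSE) {
  stopifnot(inherits(params, "sw_interaction"),
            length(r_rel) == 3, length(v_rel) == 3)
  .pair_event_cpp(as.numeric(r_rel), as.numeric(v_rel), box_length,
                  params$L, params$eps_star, bonded)
}

#' Resolve a pair event
#'
#' Applies square-well event mechanics at the moment of a boundary
#' crossing: elastic reflection at the core; kinetic-energy gain and
#' capture on well entry; escape or bounce on a well-exit attempt depending
#' on whether the normal kinetic energy exceeds the well depth. Total
#' momentum and total (kinetic + well) energy are conserved in every
#' branch.
#'
#' @param r_i,r_j,v_i,v_j Positions and velocities (length-3) with the pair
#'   exactly at the event distance.
#' @param box_length Periodic box edge.
#' @param params An [sw_interaction()].
#' @param bonded Current bond state of the pair.
#' @param event_type One of `"core_collision"`, `"well_entry"`,
#'   `"well_exit_attempt"`.
#' @return List with updated `v_i`, `v_j`, the new `bonded` state and
#'   logical `escaped`.
#' @export
resolve_event <- function(r_i, r_j, v_i, v_j, box_length, params,
                          bonded, event_type) {
  stopifnot(inherits(params, "sw_interaction"))
  .resolve_event_cpp(as.numeric(r_i), as.numeric(r_j), as.numeric(v_i),
                     as.numeric(v_j), box_length, params$L, params$eps_star,
                     bonded, event_type)
}

#' Simulation-derived activity model over a well-depth grid
#'
#' Runs the simulator at each combination of `eps_values` and `phi_grid`,
#' estimates \eqn{\ln\gamma} by Widom insertion, fits the quartic
#' representation per well depth, and assembles a [table_activity_model()]
#' ready for phase-diagram construction. This is the simulation-standard
#' counterpart of [kihara_activity_model()]; at production sampling it is
#' expensive, so the defaults here are a scaled-down protocol.
#'
#' @param L Well range.
#' @param eps_values Well depths (at least 3, bracketing any critical point
#'   of interest).
#' @param phi_grid Volume fractions for the quartic fit (at least 8).
#' @inheritParams lngamma_simulation
#' @param seed Base seed; each state point derives its own sub-seed.
#' @return A list with `model` (an `sw_model`), `table` (data.frame of all
#'   Widom estimates) and `Q_matrix`.
#' @export
simulation_activity_model <- function(L, eps_values,
                                      phi_grid = seq(0.03, 0.3, by = 0.03),
                                      N = 256, t_equil = 25, t_sample = 150,
                                      sample_interval = 3,
                                      n_insertions = 2e4, seed = 1) {
  stopifnot(length(eps_values) >= 3, length(phi_grid) >= 8)
  rows <- list()
  Q_matrix <- matrix(NA_real_, length(eps_values), 4)
  for (a in seq_along(eps_values)) {
    p <- sw_interaction(L, eps_values[a])
    lng <- numeric(length(phi_grid))
    se <- numeric(length(phi_grid))
    for (b in seq_along(phi_grid)) {
      sub_seed <- (seed * 1009L + a * 101L + b) %% .Machine$integer.max
      est <- lngamma_simulation(phi_grid[b], p, N = N, t_equil = t_equil,
                                t_sample = t_sample,
                                sample_interval = sample_interval,
                                n_insertions = n_insertions,
                                seed = sub_seed)
      lng[b] <- est$lngamma
      se[b] <- est$standard_error
      rows[[length(rows) + 1]] <-
        data.frame(L = L, eps_star = eps_values[a], phi = phi_grid[b],
                   lngamma = est$lngamma, se = est$standard_error)
    }
    curve <- activity_curve(phi_grid, lng, source = "simulation")
    Q_matrix[a, ] <- fit_quartic(curve)$Q
  }
  list(model = table_activity_model(eps_values, Q_matrix, L = L),
       table = do.call(rbind, rows),
       Q_matrix = Q_matrix)
}
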