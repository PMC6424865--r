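// Event-driven (discrete) molecular dynamics of a single-species square-well
// fluid in a cubic periodic box, with Widom-insertion estimation of the
// excess chemical potential. Reduced units throughout: hard-core diameter
// sigma, particle mass m = 1, energies in kT.
//
// Event mechanics: free flight between events; at the hard core the normal
// relative velocity reflects elastically; at the outer well boundary the
// normal kinetic energy is exchanged with the well depth (capture on entry,
// escape or bounce on exit). Pair predictions are kept per particle and
// refreshed for every particle whose stored candidate involves an updated
// partner; a periodic synchronization event re-predicts everything, which
// also bounds the horizon over which the minimum-image convention must stay
// valid.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

const double INF = std::numeric_limits<double>::infinity();
const double TINY_DT = 1e-12;

enum EventType { EV_NONE = 0, EV_CORE = 1, EV_ENTRY = 2, EV_EXIT = 3 };

struct Engine {
  int N;
  double box, L, eps, Tstar;
  bool well_active;
  std::vector<double> px, py, pz, vx, vy, vz;
  std::vector<char> bonded;              // N*N pair matrix
  std::vector<double> ev_t;              // per-particle earliest event time
  std::vector<int> ev_partner, ev_type;
  // lazy invalidation: a stored event is valid only while its partner's
  // collision stamp is unchanged (the owner's row is refreshed whenever the
  // owner's own velocity changes)
  std::vector<long long> coll_stamp;
  std::vector<long long> ev_pstamp;
  // distance pruning: an unbonded pair farther apart than cutoff cannot
  // reach the well boundary before the next full re-prediction (cutoff =
  // L*sigma + 2*vmax*sync_interval, refreshed with vmax at every full
  // re-prediction; if an event raises a speed above vmax everything is
  // re-predicted)
  double cutoff2, vmax2, sync_window;
  bool need_full_recompute;
  double t_now;
  std::mt19937_64 rng;
  // accumulators
  long long n_events, n_core, n_entry, n_exit_escape, n_exit_bounce;
  long long n_recompute_all, n_stale;
  double virial_sum, ke_time_sum, virial_t0;
  bool accumulate;
  int n_bonded_pairs;
  double max_energy_drift, e_reference;
  bool audit;

  bool is_bonded(int i, int j) const { return bonded[i * N + j] != 0; }
  void set_bonded(int i, int j, bool b) {
    bonded[i * N + j] = bonded[j * N + i] = b ? 1 : 0;
  }

  double inv_box;
  double mi(double d) const { return d - box * std::nearbyint(d * inv_box); }

  void rel(int i, int j, double& rx, double& ry, double& rz,
           double& wx, double& wy, double& wz) const {
    rx = mi(px[i] - px[j]); ry = mi(py[i] - py[j]); rz = mi(pz[i] - pz[j]);
    wx = vx[i] - vx[j]; wy = vy[i] - vy[j]; wz = vz[i] - vz[j];
  }

  // earliest future absolute time pair (i,j) crosses sigma or L*sigma
  double pair_time(int i, int j, int& type) const {
    double rx, ry, rz, wx, wy, wz;
    rel(i, j, rx, ry, rz, wx, wy, wz);
    double b = rx * wx + ry * wy + rz * wz;
    double r2 = rx * rx + ry * ry + rz * rz;
    double v2 = wx * wx + wy * wy + wz * wz;
    type = EV_NONE;
    if (v2 <= 0) return INF;
    double Ls = well_active ? L : 1.0;
    double Ls2 = Ls * Ls;
    bool inside = well_active && is_bonded(i, j);
    if (!inside && r2 > cutoff2) return INF;   // unreachable this window
    if (!inside) {
      if (b >= 0) return INF;                       // receding
      double disc = b * b - v2 * (r2 - Ls2);
      if (disc <= 0) return INF;                    // misses the boundary
      type = well_active ? EV_ENTRY : EV_CORE;
      double dt = (-b - std::sqrt(disc)) / v2;
      return t_now + (dt > TINY_DT ? dt : TINY_DT);
    }
    // inside the well: core collision if approaching and on target
    if (b < 0) {
      double disc = b * b - v2 * (r2 - 1.0);
      if (disc > 0) {
        type = EV_CORE;
        double dt = (-b - std::sqrt(disc)) / v2;
        return t_now + (dt > TINY_DT ? dt : TINY_DT);
      }
    }
    // otherwise the pair eventually reaches the outer boundary from inside
    double disc = b * b - v2 * (r2 - Ls2);
    if (disc <= 0) return INF;                      // numerically marginal
    type = EV_EXIT;
    double dt = (-b + std::sqrt(disc)) / v2;
    return t_now + (dt > TINY_DT ? dt : TINY_DT);
  }

  void recompute_min(int i) {
    ev_t[i] = INF; ev_partner[i] = -1; ev_type[i] = EV_NONE; ev_pstamp[i] = 0;
    for (int k = 0; k < N; ++k) {
      if (k == i) continue;
      int ty;
      double t = pair_time(i, k, ty);
      if (t == INF) continue;
      if (t < ev_t[i]) {
        ev_t[i] = t; ev_partner[i] = k; ev_type[i] = ty;
        ev_pstamp[i] = coll_stamp[k];
      }
      if (t < ev_t[k]) {
        ev_t[k] = t; ev_partner[k] = i; ev_type[k] = ty;
        ev_pstamp[k] = coll_stamp[i];
      }
    }
  }

  void update_cutoff() {
    double m2 = 0;
    for (int i = 0; i < N; ++i) {
      double s2 = vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i];
      if (s2 > m2) m2 = s2;
    }
    // slack of two capture-sized speed gains keeps the re-prediction
    // trigger rare while the bound stays valid for event chains
    double vb = std::sqrt(m2) + 2.0 * std::sqrt(std::fabs(eps));
    vmax2 = vb * vb;
    double Ls = well_active ? L : 1.0;
    double c = Ls + 2.0 * vb * sync_window;
    cutoff2 = c * c;           // a large cutoff simply disables pruning
    need_full_recompute = false;
  }

  void recompute_all() {
    ++n_recompute_all;
    update_cutoff();
    for (int i = 0; i < N; ++i) {
      ev_t[i] = INF; ev_partner[i] = -1; ev_type[i] = EV_NONE;
      ev_pstamp[i] = 0;
    }
    for (int i = 0; i < N; ++i)
      for (int j = i + 1; j < N; ++j) {
        int ty;
        double t = pair_time(i, j, ty);
        if (t == INF) continue;
        if (t < ev_t[i]) {
          ev_t[i] = t; ev_partner[i] = j; ev_type[i] = ty;
          ev_pstamp[i] = coll_stamp[j];
        }
        if (t < ev_t[j]) {
          ev_t[j] = t; ev_partner[j] = i; ev_type[j] = ty;
          ev_pstamp[j] = coll_stamp[i];
        }
      }
  }

  // earliest valid stored event; refreshes stale entries lazily
  int next_event_particle(double& te) {
    while (true) {
      int ei = -1; te = INF;
      for (int i = 0; i < N; ++i)
        if (ev_t[i] < te) { te = ev_t[i]; ei = i; }
      if (ei < 0) return -1;
      int j = ev_partner[ei];
      if (j >= 0 && ev_pstamp[ei] != coll_stamp[j]) {
        ++n_stale;
        recompute_min(ei);
        continue;
      }
      return ei;
    }
  }

  void advance(double dt) {
    if (dt <= 0) return;
    if (accumulate) ke_time_sum += kinetic_energy() * dt;
    for (int i = 0; i < N; ++i) {
      px[i] += vx[i] * dt; py[i] += vy[i] * dt; pz[i] += vz[i] * dt;
    }
    t_now += dt;
  }

  void wrap() {
    for (int i = 0; i < N; ++i) {
      px[i] -= box * std::floor(px[i] / box);
      py[i] -= box * std::floor(py[i] / box);
      pz[i] -= box * std::floor(pz[i] / box);
    }
  }

  double kinetic_energy() const {
    double ke = 0;
    for (int i = 0; i < N; ++i)
      ke += vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i];
    return 0.5 * ke;
  }

  double potential_energy() const { return eps * n_bonded_pairs; }

  void resolve(int i, int j, int type) {
    double rx, ry, rz, wx, wy, wz;
    rel(i, j, rx, ry, rz, wx, wy, wz);
    double d = std::sqrt(rx * rx + ry * ry + rz * rz);
    double nx = rx / d, ny = ry / d, nz = rz / d;
    double gn = wx * nx + wy * ny + wz * nz;   // normal relative velocity
    double gn_new = gn;
    if (type == EV_CORE) {
      if (gn < 0) gn_new = -gn;                // elastic reflection
      ++n_core;
    } else if (type == EV_ENTRY) {
      // crossing L*sigma inward: potential drops by -eps (eps < 0 adds KE)
      double g2 = gn * gn - 4.0 * eps;         // reduced mass 1/2
      if (g2 > 0) {
        gn_new = -std::sqrt(g2);               // continue inward
        set_bonded(i, j, true);
        ++n_bonded_pairs;
        ++n_entry;
      } else {
        gn_new = -gn;                          // bounce off repulsive shoulder
      }
    } else if (type == EV_EXIT) {
      // crossing L*sigma outward: potential rises by -eps
      double g2 = gn * gn + 4.0 * eps;
      if (g2 > 0) {
        gn_new = std::sqrt(g2);                // escape
        set_bonded(i, j, false);
        --n_bonded_pairs;
        ++n_exit_escape;
      } else {
        gn_new = -gn;                          // bounce back inside
        ++n_exit_bounce;
      }
    }
    double dg = 0.5 * (gn_new - gn);           // per-particle velocity change
    vx[i] += dg * nx; vy[i] += dg * ny; vz[i] += dg * nz;
    vx[j] -= dg * nx; vy[j] -= dg * ny; vz[j] -= dg * nz;
    ++coll_stamp[i]; ++coll_stamp[j];
    double si = vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i];
    double sj = vx[j] * vx[j] + vy[j] * vy[j] + vz[j] * vz[j];
    if (si > vmax2 || sj > vmax2) need_full_recompute = true;
    if (accumulate) virial_sum += d * dg;      // d * (dp_i . n)
    ++n_events;
    if (audit) {
      double drift = std::fabs(kinetic_energy() + potential_energy()
                               - e_reference);
      double scale = std::fabs(e_reference) > 1 ? std::fabs(e_reference) : 1.0;
      if (drift / scale > max_energy_drift) max_energy_drift = drift / scale;
    }
  }

  void post_event_refresh(int i, int j) {
    // stored events referencing i or j are invalidated by the stamp bump
    // and refreshed lazily at selection time
    recompute_min(i);
    recompute_min(j);
  }

  void rebuild_bond_table() {
    std::fill(bonded.begin(), bonded.end(), 0);
    n_bonded_pairs = 0;
    if (!well_active) return;
    double L2 = L * L;
    for (int i = 0; i < N; ++i)
      for (int j = i + 1; j < N; ++j) {
        double rx = mi(px[i] - px[j]), ry = mi(py[i] - py[j]),
               rz = mi(pz[i] - pz[j]);
        double r2 = rx * rx + ry * ry + rz * rz;
        if (r2 < L2) { set_bonded(i, j, true); ++n_bonded_pairs; }
      }
  }

  void draw_velocities() {
    std::normal_distribution<double> nd(0.0, std::sqrt(Tstar));
    double sx = 0, sy = 0, sz = 0;
    for (int i = 0; i < N; ++i) {
      vx[i] = nd(rng); vy[i] = nd(rng); vz[i] = nd(rng);
      sx += vx[i]; sy += vy[i]; sz += vz[i];
    }
    for (int i = 0; i < N; ++i) {           // zero net momentum
      vx[i] -= sx / N; vy[i] -= sy / N; vz[i] -= sz / N;
      ++coll_stamp[i];
    }
  }
};

void init_fcc(Engine& E) {
  int m = (int)std::ceil(std::cbrt(E.N / 4.0));
  while (4 * m * m * m < E.N) ++m;
  double a = E.box / m;
  double nn = a / std::sqrt(2.0);
  if (nn < 1.0 + 1e-9)
    stop("cannot place %d non-overlapping particles at this volume fraction "
         "(fcc nearest-neighbour distance %f < sigma)", E.N, nn);
  static const double basis[4][3] = {
    {0.0, 0.0, 0.0}, {0.5, 0.5, 0.0}, {0.5, 0.0, 0.5}, {0.0, 0.5, 0.5}};
  int idx = 0;
  for (int ix = 0; ix < m && idx < E.N; ++ix)
    for (int iy = 0; iy < m && idx < E.N; ++iy)
      for (int iz = 0; iz < m && idx < E.N; ++iz)
        for (int b = 0; b < 4 && idx < E.N; ++b) {
          E.px[idx] = (ix + basis[b][0]) * a;
          E.py[idx] = (iy + basis[b][1]) * a;
          E.pz[idx] = (iz + basis[b][2]) * a;
          ++idx;
        }
}

double min_pair_distance(const Engine& E) {
  double best = INF;
  for (int i = 0; i < E.N; ++i)
    for (int j = i + 1; j < E.N; ++j) {
      double rx = E.mi(E.px[i] - E.px[j]), ry = E.mi(E.py[i] - E.py[j]),
             rz = E.mi(E.pz[i] - E.pz[j]);
      double r2 = rx * rx + ry * ry + rz * rz;
      if (r2 < best) best = r2;
    }
  return std::sqrt(best);
}

} // namespace

// [[Rcpp::export(name = ".dmd_run_cpp")]]
List dmd_run_cpp(int N, double phi, double L, double eps, double Tstar,
                 double t_equil, double t_sample, double sample_interval,
                 double thermostat_interval, bool thermostat,
                 double sync_interval, int seed) {
  if (N < 2) stop("N must be at least 2");
  if (phi <= 0 || phi >= 1) stop("phi must lie in (0, 1)");
  Engine E;
  E.N = N; E.L = L; E.eps = eps; E.Tstar = Tstar;
  E.well_active = (eps != 0.0) && (L > 1.0);
  E.box = std::cbrt(N * M_PI / (6.0 * phi));
  E.inv_box = 1.0 / E.box;
  if (E.box < 2.0 * L)
    stop("box too small for the minimum-image convention at this N and phi");
  E.px.resize(N); E.py.resize(N); E.pz.resize(N);
  E.vx.resize(N); E.vy.resize(N); E.vz.resize(N);
  E.bonded.assign((size_t)N * N, 0);
  E.ev_t.assign(N, INF); E.ev_partner.assign(N, -1); E.ev_type.assign(N, 0);
  E.coll_stamp.assign(N, 0); E.ev_pstamp.assign(N, 0);
  E.sync_window = sync_interval;
  E.cutoff2 = INF; E.vmax2 = 0; E.need_full_recompute = false;
  E.t_now = 0;
  E.rng.seed((uint64_t)seed * 0x9E3779B97F4A7C15ULL + 1ULL);
  E.n_events = E.n_core = E.n_entry = E.n_exit_escape = E.n_exit_bounce = 0;
  E.n_recompute_all = E.n_stale = 0;
  E.virial_sum = 0; E.ke_time_sum = 0; E.accumulate = false;
  E.max_energy_drift = 0; E.audit = !thermostat;

  init_fcc(E);
  E.draw_velocities();
  E.rebuild_bond_table();
  E.e_reference = E.kinetic_energy() + E.potential_energy();
  E.recompute_all();

  double t_end = t_equil + t_sample;
  double t_sync = sync_interval;
  double t_therm = thermostat ? thermostat_interval : INF;
  double t_snap = t_equil;             // first snapshot at start of sampling
  double sample_t0 = NA_REAL;
  bool sampling_started = false;

  List snapshots;
  std::vector<double> snap_min_dist;

  long long guard = 0;
  const long long guard_max = 500000000LL;
  while (true) {
    if (++guard > guard_max) stop("event budget exceeded");
    double te;
    int ei = E.next_event_particle(te);
    // priority on ties: end > snapshot > thermostat > sync > pair event
    // (ties resolved toward re-prediction, which is always safe)
    if (t_end <= te && t_end <= t_sync && t_end <= t_therm &&
        t_end <= t_snap) {
      E.advance(t_end - E.t_now);
      break;
    }
    double tn = std::min(std::min(te, t_sync), std::min(t_therm, t_snap));
    E.advance(tn - E.t_now);
    if (t_snap <= te && t_snap <= t_sync && t_snap <= t_therm) {
      if (!sampling_started) {
        sampling_started = true;
        E.accumulate = true;
        sample_t0 = E.t_now;
        E.virial_sum = 0; E.ke_time_sum = 0;
      }
      E.wrap();
      NumericMatrix pos(E.N, 3), vel(E.N, 3);
      for (int i = 0; i < E.N; ++i) {
        pos(i, 0) = E.px[i]; pos(i, 1) = E.py[i]; pos(i, 2) = E.pz[i];
        vel(i, 0) = E.vx[i]; vel(i, 1) = E.vy[i]; vel(i, 2) = E.vz[i];
      }
      snapshots.push_back(List::create(_["positions"] = pos,
                                       _["velocities"] = vel,
                                       _["time"] = E.t_now));
      snap_min_dist.push_back(min_pair_distance(E));
      t_snap += sample_interval;
      E.recompute_all();               // wrap() moved coordinates
      continue;
    }
    if (t_therm <= te && t_therm <= t_sync) {
      E.draw_velocities();
      t_therm += thermostat_interval;
      E.recompute_all();
      continue;
    }
    if (t_sync <= te) {
      E.wrap();
      t_sync += sync_interval;
      E.recompute_all();
      continue;
    }
    int j = E.ev_partner[ei];
    int ty = E.ev_type[ei];
    E.resolve(ei, j, ty);
    if (E.need_full_recompute) E.recompute_all();
    else E.post_event_refresh(ei, j);
  }

  double t_sampled = sampling_started ? (E.t_now - sample_t0) : 0.0;
  double T_meas = t_sampled > 0
    ? E.ke_time_sum / t_sampled * 2.0 / (3.0 * E.N) : NA_REAL;
  double Z = (t_sampled > 0 && T_meas > 0)
    ? 1.0 + E.virial_sum / (3.0 * E.N * T_meas * t_sampled) : NA_REAL;

  double sx = 0, sy = 0, sz = 0;
  for (int i = 0; i < E.N; ++i) { sx += E.vx[i]; sy += E.vy[i]; sz += E.vz[i]; }

  return List::create(
    _["snapshots"] = snapshots,
    _["box_length"] = E.box,
    _["N"] = E.N, _["phi"] = phi, _["L"] = L, _["eps_star"] = eps,
    _["temperature_target"] = Tstar,
    _["temperature_measured"] = T_meas,
    _["Z_virial"] = Z,
    _["t_sampled"] = t_sampled,
    _["n_events"] = (double)E.n_events,
    _["n_core"] = (double)E.n_core,
    _["n_entry"] = (double)E.n_entry,
    _["n_exit_escape"] = (double)E.n_exit_escape,
    _["n_exit_bounce"] = (double)E.n_exit_bounce,
    _["max_energy_drift"] = E.max_energy_drift,
    _["min_snapshot_distance"] = snap_min_dist.empty() ? NA_REAL :
      *std::min_element(snap_min_dist.begin(), snap_min_dist.end()),
    _["net_momentum"] = std::sqrt(sx * sx + sy * sy + sz * sz),
    _["seed"] = seed,
    _["n_recompute_all"] = (double)E.n_recompute_all,
    _["n_stale"] = (double)E.n_stale);
}

// [[Rcpp::export(name = ".widom_cpp")]]
List widom_cpp(List snapshots, double box, double L, double eps,
               int n_insertions, int seed) {
  int S = snapshots.size();
  if (S < 1) stop("need at least one snapshot");
  std::mt19937_64 rng((uint64_t)seed * 0x9E3779B97F4A7C15ULL + 17ULL);
  std::uniform_real_distribution<double> U(0.0, 1.0);
  NumericVector mean_w(S);
  NumericVector frac_overlap(S);
  double L2 = L * L;
  for (int s = 0; s < S; ++s) {
    List snap = snapshots[s];
    NumericMatrix pos = snap["positions"];
    int N = pos.nrow();
    double sum_w = 0;
    int n_overlap = 0;
    for (int ins = 0; ins < n_insertions; ++ins) {
      double x = U(rng) * box, y = U(rng) * box, z = U(rng) * box;
      int n_well = 0;
      bool overlap = false;
      for (int i = 0; i < N; ++i) {
        double dx = x - pos(i, 0); dx -= box * std::round(dx / box);
        double dy = y - pos(i, 1); dy -= box * std::round(dy / box);
        double dz = z - pos(i, 2); dz -= box * std::round(dz / box);
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 < 1.0) { overlap = true; break; }
        if (r2 < L2) ++n_well;
      }
      if (overlap) { ++n_overlap; continue; }   // Boltzmann factor exactly 0
      sum_w += std::exp(-eps * n_well);
    }
    mean_w[s] = sum_w / n_insertions;
    frac_overlap[s] = (double)n_overlap / n_insertions;
  }
  return List::create(_["mean_weight"] = mean_w,
                      _["frac_overlap"] = frac_overlap,
                      _["n_insertions"] = n_insertions,
                      _["seed"] = seed);
}

// [[Rcpp::export(name = ".pair_event_cpp")]]
List pair_event_cpp(NumericVector r_rel, NumericVector v_rel, double box,
                    double L, double eps, bool bonded) {
  Engine E;
  E.N = 2; E.L = L; E.eps = eps; E.Tstar = 1;
  E.well_active = (eps != 0.0) && (L > 1.0);
  E.box = box; E.inv_box = 1.0 / box;
  E.coll_stamp.assign(2, 0);
  E.cutoff2 = INF; E.vmax2 = INF; E.sync_window = 0;
  E.need_full_recompute = false;
  E.px = {r_rel[0], 0}; E.py = {r_rel[1], 0}; E.pz = {r_rel[2], 0};
  E.vx = {v_rel[0], 0}; E.vy = {v_rel[1], 0}; E.vz = {v_rel[2], 0};
  E.bonded.assign(4, 0);
  E.t_now = 0;
  E.n_bonded_pairs = 0;
  if (bonded && E.well_active) { E.set_bonded(0, 1, true); E.n_bonded_pairs = 1; }
  double r2 = 0;
  for (int k = 0; k < 3; ++k) {
    double d = E.mi(r_rel[k]);
    r2 += d * d;
  }
  if (r2 < 1.0 - 1e-9) stop("overlapping input state");
  int ty;
  double t = E.pair_time(0, 1, ty);
  CharacterVector types = CharacterVector::create(
    "none", "core_collision", "well_entry", "well_exit_attempt");
  return List::create(_["time"] = t,
                      _["type"] = as<std::string>(types[ty]));
}

// [[Rcpp::export(name = ".resolve_event_cpp")]]
List resolve_event_cpp(NumericVector r_i, NumericVector r_j,
                       NumericVector v_i, NumericVector v_j, double box,
                       double L, double eps, bool bonded,
                       std::string event_type) {
  Engine E;
  E.N = 2; E.L = L; E.eps = eps; E.Tstar = 1;
  E.well_active = (eps != 0.0) && (L > 1.0);
  E.box = box; E.inv_box = 1.0 / box;
  E.coll_stamp.assign(2, 0);
  E.cutoff2 = INF; E.vmax2 = INF; E.sync_window = 0;
  E.need_full_recompute = false;
  E.px = {r_i[0], r_j[0]}; E.py = {r_i[1], r_j[1]}; E.pz = {r_i[2], r_j[2]};
  E.vx = {v_i[0], v_j[0]}; E.vy = {v_i[1], v_j[1]}; E.vz = {v_i[2], v_j[2]};
  E.bonded.assign(4, 0);
  E.t_now = 0; E.accumulate = false; E.audit = false;
  E.n_events = E.n_core = E.n_entry = E.n_exit_escape = E.n_exit_bounce = 0;
  E.n_recompute_all = E.n_stale = 0;
  E.n_bonded_pairs = 0;
  if (bonded && E.well_active) { E.set_bonded(0, 1, true); E.n_bonded_pairs = 1; }
  int ty;
  if (event_type == "core_collision") ty = EV_CORE;
  else if (event_type == "well_entry") ty = EV_ENTRY;
  else if (event_type == "well_exit_attempt") ty = EV_EXIT;
  else stop("unknown event type '%s'", event_type.c_str());
  if (ty == EV_ENTRY && bonded)
    stop("inconsistent bonded bookkeeping: entry event for a bonded pair");
  if ((ty == EV_EXIT || ty == EV_CORE) && E.well_active && !bonded)
    stop("inconsistent bonded bookkeeping: in-well event for an unbonded pair");
  E.resolve(0, 1, ty);
  return List::create(
    _["v_i"] = NumericVector::create(E.vx[0], E.vy[0], E.vz[0]),
    _["v_j"] = NumericVector::create(E.vx[1], E.vy[1], E.vz[1]),
    _["bonded"] = E.well_active ? E.is_bonded(0, 1) : false,
    _["escaped"] = E.n_exit_escape > 0);
}
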