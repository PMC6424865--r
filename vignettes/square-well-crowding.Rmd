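---
title: "Square-well models of non-specific protein interactions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Square-well models of non-specific protein interactions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sqwell)
```

## The model

In a concentrated protein solution every molecule interacts sterically with
its neighbours, and usually also through weaker, longer-ranged attractions or
repulsions. `sqwell` represents a single globular macrosolute species as a
fluid of spheres interacting through the square-well potential of mean force:
infinitely repulsive below the contact distance (hard-core diameter
$\sigma = 2r$), a constant well of depth $\epsilon^* = \epsilon/kT$ out to
$L$ times the contact distance, and zero beyond. Two dimensionless parameters
($L$, $\epsilon^*$) therefore carry all of the interaction physics; solution
composition enters as the solute volume fraction $\phi$, connected to molar
concentration by $\phi = c M \bar v / 1000$.

All internal thermodynamics is computed in reduced units ($\sigma = 1$,
$kT = 1$); molar units appear only at the conversion boundary. This mirrors
how the results are naturally plotted — everything is a function of
$(\phi, \epsilon^*)$.

The central quantity is the thermodynamic activity coefficient: $\ln\gamma$
is the excess chemical potential of a solute molecule in kT units. From its
concentration dependence follow the measurable consequences of crowding:

* static light scattering, $I \propto \phi / (1 + \phi\, d\ln\gamma/d\phi)$;
* sedimentation-equilibrium apparent molar mass,
  $M_{app} = M / (1 + \phi\, d\ln\gamma/d\phi)$;
* osmotic pressure, $\Pi \propto \phi + \int_0^\phi \phi^*
  (d\ln\gamma/d\phi^*)\, d\phi^*$;
* crowding factors $\Gamma$ that convert thermodynamic equilibrium constants
  of folding or binding reactions into apparent, concentration-based ones.

## Two routes to ln gamma

**Analytical (Kihara+).** The activity coefficient is partitioned into a
hard-core part and a soft part, $\ln\gamma = \ln\gamma_{hard} +
\ln\gamma_{soft}$. The hard part is the scaled-particle-theory (SPT) excess
chemical potential of an identical hard sphere, obtained in closed form from
$Z(\phi) = (1+\phi+\phi^2)/(1-\phi)^3$. The soft part is a truncated virial
series $2 B_{2,soft}\rho + \tfrac{3}{2} B_{3,soft}\rho^2$ built from the
exact square-well virial coefficients with their hard-sphere parts
subtracted. The factors 2 and $3/2$ are the McMillan–Mayer convention for
the activity expansion; we fixed this convention because it is the unique
choice under which the pure hard-sphere limit reproduces the SPT leading
slope $d\ln\gamma/d\phi \to 8$. A Carnahan–Starling hard reference is
available as an option (`hard = "cs"`) but is never the default.

The square-well $B_3$ closed form is a cubic polynomial in the well Mayer
factor $f = e^{-\epsilon^*} - 1$ with piecewise-polynomial coefficients in
$L$ (the triple-overlap geometry changes at $L = 2$). We verified the
transcription for $1 \le L \le 2$ against a seeded Monte-Carlo evaluation of
the irreducible three-body cluster integral, re-derived the $L \ge 2$ branch
from that integral symbolically after the form we first transcribed from the
literature failed the oracle at $L = 2.5$, and treat the Monte-Carlo oracle
— not any printed formula — as the source of truth in the test suite.

**Numerical (DMD + Widom).** Event-driven (discrete) molecular dynamics
propagates the square-well fluid exactly from collision to collision: the
hard core reflects the normal relative velocity; crossing the outer well
boundary exchanges kinetic energy with the well depth (capture on entry;
escape or bounce on exit attempts). The engine conserves momentum exactly
and total energy to near machine precision between thermostat events, which
the tests audit. $\ln\gamma$ is then estimated by Widom insertion: random
ghost positions score $e^{-\Delta U}$, with hard-core overlaps contributing
exactly zero, and $\ln\gamma = -\ln\langle e^{-\Delta U}\rangle$ with a
block standard error over snapshots.

Design choices in the simulator, made where the procedure was genuinely
open:

* **Ensemble.** NVT via an Andersen-style thermostat (full Maxwell–Boltzmann
  velocity redraw every 0.5 reduced time units). Simple and rigorous for
  equilibrium averages; it is disabled for the conservation audits.
* **Initialization.** Face-centred cubic lattice (feasible to
  $\phi \approx 0.45$ for typical N before the melt becomes unreliable),
  Maxwell–Boltzmann velocities at $T^* = 1$, zero net momentum.
* **Event bookkeeping.** Per-particle earliest-event records with lazy
  invalidation by collision stamps, and a periodic synchronization event
  (every 0.1 time units) that re-predicts all pairs; the synchronization
  window also bounds the horizon over which the minimum-image convention
  must remain valid. Grazing or coincident events are pushed forward by
  $10^{-12}$ reduced time and re-predicted, which avoids infinite event
  loops.
* **Pressure.** The compressibility factor is accumulated from collision
  impulses (the virial of the momentum transfers), normalized by the
  time-averaged measured kinetic temperature.

## The quartic representation and colligative properties

Over the window $0 < \phi \le 0.4$, $\ln\gamma(\phi)$ from either route is
condensed into a zero-intercept quartic $Q_1\phi + Q_2\phi^2 + Q_3\phi^3 +
Q_4\phi^4$ by linear least squares on a grid of step 0.01 (40 points; the
fit RMS is reported and is below $10^{-2}$ even for the stiff SPT curve).
The quartic gives $\phi\, d\ln\gamma/d\phi$ and its integral in closed form,
and every colligative observable and phase construction downstream consumes
those two polynomials. This fitted route is the package default because it
is the route behind the reference numbers; the exact analytic derivative of
the Kihara+ model is exposed alongside (`dlngamma_kihara_plus_dphi`) for
users who want the cleaner computation.

Evaluation outside the fit window warns and flags rather than failing,
because coexistence branches legitimately exceed $\phi = 0.4$. Observables
with $|1 + \phi\, d\ln\gamma/d\phi| < 10^{-6}$ are reported as flagged
non-finite values rather than huge floats — that denominator vanishing is
the physical divergence of scattering at the onset of demixing.

## Phase separation

For attraction stronger than a critical depth the osmotic pressure becomes
non-monotonic and the solution demixes into dilute and concentrated phases:

* the **spinodal** pair solves $d\Pi/d\phi = 0$ (roots of a quartic
  polynomial on the default path);
* the **binodal** pair solves simultaneous equality of osmotic pressure and
  chemical potential $\mu/kT = \ln\phi + \ln\gamma + const$ — the standard
  coexistence construction under the McMillan–Mayer gas analogy; a Maxwell
  equal-area construction in the $(\Pi, -1/\phi)$ plane is implemented
  independently (`binodal_maxwell`) and the two agree to $10^{-3}$ in
  $\phi$ in the tests.
* the **critical point** solves $\partial\Pi/\partial\phi =
  \partial^2\Pi/\partial\phi^2 = 0$ in $(\phi, \epsilon^*)$, by a bisection
  scan over the well depth followed by a damped two-dimensional Newton
  iteration with numerical $\epsilon^*$-derivatives (search box
  $\phi \in (0.02, 0.35)$, $\epsilon^* \in (-2.5, -0.3)$ by default).

The binodal solver inverts $\mu$ on each stable branch by bracketing and
then drives the pressure mismatch to zero (a nested one-dimensional
construction that cannot jump branches), finishing with a Newton polish to
$10^{-10}$. When the concentrated branch leaves the quartic window the
solver switches to the exact closed-form Kihara+ thermodynamics
(`method = "auto"`); the quartic extrapolated that far is unreliable, and
the model's own high-concentration pressure is already known to be
systematically high, so the deep-quench branch is reported with an
`extrapolated` flag and excluded from the polynomial curves fitted through
the diagram (the critical point anchors those fits instead).

Full diagrams tabulate both curves on a well-depth grid (default: from
$\epsilon^*_{crit} - 0.6$ up to $\epsilon^*_{crit} - 0.02$ in steps of
0.02, computed after the critical point), apply the lever rule inside the
coexistence region, and can be rescaled to reduced coordinates
$(\phi/\phi_{crit},\, T_{rel}/T_{crit})$ with $T_{rel} \equiv -1/\epsilon^*$,
in which curves for different well ranges nearly collapse near the apex.

```{r example}
model <- kihara_activity_model(L = 1.25)
critical_point(model)
```

## What the synthetic data emulate — and what they do not

The simulator generates equilibrium configurations of the idealized model
itself: monodisperse spheres, isotropic pairwise square wells, no solvent
degrees of freedom, no electrostatics, no anisotropy or patchiness, and no
polydispersity. Passing tests therefore demonstrate that the analytical
model and the simulation agree about the *square-well fluid*, and that the
thermodynamic machinery is internally consistent — not that any particular
protein follows the model. Comparisons to experimental scattering,
osmometry or coexistence data are deliberately out of scope; the species
parameters ($M$, $\bar v$) enter only through the concentration conversion.

Problem sizes were chosen as desk-scale defaults: $N = 256$ particles,
equilibration 50 and sampling 200 reduced time units with $10^4$ insertions
per snapshot for single state points. The simulation-derived phase diagrams
in the acceptance suite run a deliberately reduced protocol (10 volume
fractions up to 0.30, three well depths per well range, sampling 120 time
units after 75 of equilibration — equilibration was lengthened after a
stationarity check showed the lattice melt still relaxing at the most
attractive state points). At this scale the critical-point estimates carry
visible stochastic scatter (of order 0.01–0.03 in $\phi_{crit}$ and
0.03–0.08 in $\epsilon^*_{crit}$ between seeds) plus finite-size and
near-critical Widom bias, so they reproduce reference values from long
simulation campaigns only to within bands of that order, while the
deterministic analytical pipeline reproduces its reference critical points
essentially exactly (e.g. $(\phi_{crit}, \epsilon^*_{crit}) \approx
(0.13, -1.33)$ for $L = 1.25$ and $(0.12, -0.80)$ for $L = 1.5$).

## Numerical choices and edge cases

* Hard-core overlap is a sentinel whose Boltzmann factor is exactly zero;
  it never leaks into arithmetic.
* The branch boundaries of the pair potential are half-open exactly as
  defined: contact is inside the well, the outer boundary outside.
* $\epsilon^* > 0$ (a repulsive shoulder) is accepted by all analytic
  routines and by the event mechanics (entry then requires sufficient
  normal kinetic energy), although the attractive regime is the model's
  domain of interest.
* Monte-Carlo oracles record their seed and sample count; below $10^5$
  samples the result carries a warning flag.
* The spinodal reports an error, not a silent answer, if more than two
  roots appear in the physical window (a sign the quartic is being used
  far outside its validity) or if the unstable region extends past the
  window.
* Concentration conversions validate $0 \le \phi < 1$ and positive molar
  mass and exclusion volume; degenerate fit grids (rank-deficient quartic
  design) are errors rather than silent least-squares answers.

## Known limitations

Single-species solutions only: cross-interaction parameters for mixtures
are deliberately not modelled. Temperature enters only through
$\epsilon^*$ (and the fixed $T_{rel} = -1/\epsilon^*$ transform); there is
no explicit $\epsilon(T)$ mapping. The truncation of the soft term after
$B_3$ underestimates attraction effects at high concentration, which is
why the concentrated binodal branch from the analytical model should not
be read quantitatively; the same truncation shows up directly in the
model-vs-simulation comparison, where at the densest, most attractive
state point tested ($\phi = 0.25$, $\epsilon^* = -1$, $L = 1.25$) the
Widom $\ln\gamma$ sits about 0.6 kT below the Kihara+ value (a deviation
confirmed by an independent Metropolis Monte-Carlo check during
development, and small on the several-kT scale over which $\ln\gamma$
varies). Solid–liquid equilibria (solubility) and demixing
kinetics are out of scope.
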