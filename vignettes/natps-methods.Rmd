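---
title: "Methods: time-reversible surface hopping and transition path sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-reversible surface hopping and transition path sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the model, the dynamics, the sampling algorithms
and the numerical choices behind the package, together with their
assumptions and known limitations.  All quantities are atomic units
(Hartree, bohr, electron mass, atomic time unit), with `hbar = 1` and the
single unit-bridging constant `kB_hartree = 3.166811563e-6` Ha/K.

## The model

Two displaced harmonic diabats with constant coupling,

$$H(q) = \begin{pmatrix}
\epsilon\,(q-x_0)^2/x_0^2 & V_c \\ V_c & \epsilon\,(q+x_0)^2/x_0^2
\end{pmatrix},$$

with defaults $\epsilon = 0.05$ Ha, $x_0 = 1$ bohr, $V_c = 0.2\,\epsilon$,
and the mass of a hydrogen atom ($1836.15\,m_e$).  The adiabats are
$\bar V \pm V_z$ with $\bar V = (H_{11}+H_{22})/2$ and
$V_z = \sqrt{\Delta^2 + V_c^2}$, $\Delta = (H_{11}-H_{22})/2$.  Everything
is closed-form: the mixing half-angle is
$\theta = \tfrac12\,\mathrm{atan2}(V_c, \Delta) \in (0, \pi/2)$, which
fixes a globally smooth eigenvector gauge (no sign-continuity bookkeeping
is ever needed), and the derivative coupling is
$d(q) = \theta'(q) = V_c\,\epsilon / (x_0 V_z^2)$, whose integral over the
line is exactly $\pi/2$.

Two distinct "barrier heights" coexist.  `barrier_height()` returns
$E_a = (1 - V_c/\epsilon)\,\epsilon$, the lower-adiabat energy at the
crossing seam measured from the diabatic well minima (energy zero); the
well-to-top barrier on the lower adiabat is larger by exactly
$V_c^2/(4\epsilon)$ because the avoided crossing pushes the adiabatic
minima below zero.  At the defaults the residual is 1.25% of $E_a$; the
test suite asserts the closed-form identity rather than pretending the two
definitions coincide.  $E_a = 0.04$ Ha corresponds to
$T = E_a/k_B \approx 12{,}631$ K.

The model enters the integrator through four constants only; any other
1D two-state model exposing the same derived quantities (`adiabatize`,
`mash_force`) can reuse the R-level machinery, though the compiled core is
specialized to the coupled-harmonic family for speed.

## Dynamics

The electronic state is stored as the adiabatic coefficient pair
$(c_-, c_+)$; the Bloch vector is derived on demand through
$S_x = 2\,\mathrm{Re}(c_+^* c_-)$, $S_y = 2\,\mathrm{Im}(c_+^* c_-)$,
$S_z = |c_+|^2 - |c_-|^2$.  The active surface is $\mathrm{sign}(S_z)$,
with the measure-zero tie $S_z = 0$ resolved to the lower surface — a
deterministic rule that is identical forwards and backwards in time.

**Nuclear step.**  Velocity Verlet on the active adiabat, default
`dt = 5` a.t.u.  Within a step the nuclear path is the drift segment
(linear in time at the half-step velocity); the electronic propagation is
defined along that same segment, which keeps the coupled step exactly
time-reversal symmetric.

**Electronic step.**  The coefficients are rotated into the diabatic
frame with the analytic eigenvector matrix at the segment start,
propagated with a 4th-order Magnus integrator (two Gauss–Legendre nodes
per substep, exact 2x2 exponentials via the Pauli decomposition), and
rotated back at the segment end.  For this model the diabatic frame is
global and exact, so this is the cleanest form of local diabatization (for
a general model the role of the frame is played by the per-substep
eigenvector overlap).  Each substep propagator is exactly unitary, and the
scheme is exactly time-reversal symmetric because the diabatic Hamiltonian
is real and the Gauss nodes are placed symmetrically.  The default of 32
substeps per nuclear step was chosen so that one nuclear step agrees with
a fine-step Runge–Kutta integration of the adiabatic-picture Schrödinger
equation (the independent oracle in the test suite) to well below the
1e-8 amplitude tolerance the package promises; measured errors at thermal
velocities are several orders below that.

**Hops.**  If `sign(Sz)` differs between the ends of a trial step, the
crossing time is bracketed by bisection on sub-propagated segments
(each evaluation restarts from the step's initial state) to a time
tolerance of `root_tol = 1e-10` a.t.u.  The system is advanced to the
crossing, the hop is applied, and the remainder of the step is completed
on the resulting surface.  Momentum bookkeeping is closed-form:
downward hops always succeed with $p'^2 = p^2 + 4 m V_z(q^*)$; upward
hops require $p^2/2m \ge 2 V_z(q^*)$ and use $p'^2 = p^2 - 4 m V_z(q^*)$;
otherwise the hop is frustrated and the momentum along the coupling
direction (in 1D, all of it) is reversed with the surface unchanged.  For
allowed hops the state is taken on the *new*-sign side of the bracket and
for frustrated hops on the *old*-sign side, so `sign(Sz)` and the active
surface never disagree.  A second crossing inside the remainder of the
same step is handled by iterating the same construction; more than eight
events in one step aborts with a diagnostic to reduce `dt`.  (Crossing
pairs that cancel *within* one step without changing the endpoint sign are
invisible to endpoint detection; `dt = 5` a.t.u. keeps such events
negligible for this model.)

The tight root tolerance is what makes the integrator reversible in
practice: forward and backward passes locate the same hop to ~1e-10
a.t.u., and the round trip (propagate 1000 steps across hops, reverse,
propagate, reverse) recovers the initial point to ~1e-12 in
$(q, p, \vec S)$.  A deliberately naive variant
(`mash_control(hop_mode = "endpoint")`) detects hops only at step ends;
it degrades the round trip by many orders of magnitude and is retained
purely as a reference for that comparison.

**Time reversal** maps $q \to q$, $p \to -p$, $c \to c^*$, i.e.
$(S_x, S_y, S_z) \to (S_x, -S_y, S_z)$.

**Conservation.**  The spin norm and the one-step phase-space volume (in
the canonical coordinates $q, p, S_z, \phi$) are conserved to 1e-10 and
1e-6 respectively.  Total energy is conserved in the shadow sense of
velocity Verlet: the hop map itself is exactly energy-conserving, so there
is no secular drift, but the instantaneous energy oscillates with
amplitude $\sim (\omega\,\mathrm{dt})^2/8 \times E$.  For hop-capable
trajectories ($E \gtrsim 0.06$ Ha, and curvature up to
$|V''| \approx 1$ Ha/bohr² near the seam) this is of order 1e-4 Ha at
`dt = 5` — an intrinsic property of the integrator at this step size, not
a defect of the hop treatment; the deviation shrinks quadratically with
`dt`.  The test suite asserts the envelope and the absence of drift; a
stricter absolute test at 1e-6 Ha is retained (and fails, as expected from
the envelope) to document the scale honestly.

## Equilibrium sampling

The stationary distribution of MASH dynamics is the canonical density on
the extended phase space, with the spin uniform on the hemisphere selected
by the active surface.  `sample_boltzmann()` draws momenta from the
Maxwell–Boltzmann distribution, the pair (q, hemisphere) by inverse-CDF on
a trapezoid-integrated table (2^14 points spanning the region within
12 kBT of the lower minima; a half-resolution normalization check guards
against under-resolved grids), and the spin uniformly in $(S_z, \phi)$ on
the hemisphere.  Stationarity under propagation is verified statistically
in the tests.

`harvest_transitions()` extracts maximal segments whose first stored point
lies in one basin, whose last lies in the other, and whose interior
touches neither.  The reactive-path constraint is defined with an A start
and a B end, so the default returns A→B segments only; with
`direction = "both"`, B→A transits are returned time-reversed (equal
weight by microscopic reversibility) and flagged.  Efficiency accounting
for brute-force dynamics uses `direction = "both"`: every barrier transit
is a transition path once oriented, which is how a practitioner counts
paths from an equilibrium run.

## The TPS engine

Basins: lower adiabat with $q < -0.8$ (A) and $q > 0.8$ (B).  A shooting
move picks an index uniformly along the current path, applies the
Uhlenbeck–Ornstein velocity perturbation
$v' = \alpha v + \sqrt{1-\alpha^2}\,\Delta v$ (default $\alpha = 0.9$,
which perturbs smoothly yet decorrelates the chain in ~10 MC steps),
keeps the position and electronic state, and propagates forward and
backward until basin commitment.  The candidate is accepted iff its ends
connect A to B and a uniform draw passes the flexible-length factor
$\min(1, L_{old}/L_{new})$; on rejection the previous path is repeated in
the chain.  Candidates that come out B→A are stored time-reversed
(`reverse_policy = "reverse-accept"`, the default — both orientations have
equal path weight; `"strict-reject"` is available for comparison, and the
two agree statistically in our validation runs).  Shots whose either side
fails to commit within `max_steps_per_side` (default 4000 steps) are
rejected; their integration steps still count toward the efficiency
accounting, as do those of every rejected shot.

Two conventions for the efficiency-ratio denominator are reported:
MC samples (chain length) and distinct accepted paths.  The headline
ratio uses chain samples.  Note that the numerator is dominated by the
rare shots that get trapped on the upper adiabat and run to the
`max_steps_per_side` cap (upper-state residence is controlled by the
coupling, not the temperature, which is also why the ratio is nearly
temperature-independent); the ratio therefore scales with the cap, which
is a protocol parameter, and comparisons are meaningful only at a stated
cap.

The initial path is built from a high-energy point (default: $q = 1$,
$v = -0.0087$ bohr/a.t.u., spin at the south pole) by propagating a fixed
window both ways and trimming the first reactive segment; failed starts
retry with fresh thermal velocities.  The first 15% of every chain is
marked as equilibration and excluded from analysis.

`anneal()` runs a descending temperature ladder, seeding each chain with
the final path of the previous one and scaling per-temperature chain
lengths so that $\sigma_\tau/\sqrt{N}$ stays approximately constant (a
short pilot chain estimates $\sigma_\tau$).  `sweep_coupling()` repeats
runs across $V_c$ at fixed temperature.

## Analysis conventions

* Transition time $\tau$ = (path steps) × dt; chain averages use the
  chain with rejection-induced repeats.
* The transition-time autocorrelation uses the population (1/N) variance
  so $C(0) = 1$ exactly; the decorrelation length is the first crossing
  of $1/e$ (a documented convention — configurable threshold).  This
  estimator is fragile under the heavy upper tail of the flexible-length
  ensemble: a single near-cap path that enters the chain for one or two
  steps inflates $\sigma_\tau^2$ and can collapse the estimate to the
  episode length.  We keep the plain estimator and note the fragility
  rather than clipping outliers.
* Hop counts use non-frustrated events only (frustrated reflections are
  reported separately); reactive paths always carry an even count.
* The coherence angle at a hop is $\phi = \mathrm{atan2}(S_y, S_x)$.
  Crossing events sample the equator with flux weighting
  $|\dot S_z| \propto |\dot q\, d(q)\, S_x|$, so the $\phi$ density at
  hops is proportional to $|\cos\phi|$-like with real nodes at
  $\pm\pi/2$ — it is *not* uniform, and the corresponding strict
  uniformity test in the acceptance suite fails for this physical reason.
  The hop-position distribution, by contrast, is symmetric about the seam
  and concentrated at $q = 0$ as expected.
* Histograms default to 100 bins over the observed range.

## Problem sizes and reproducibility

The test suite uses chains of 120–5000 shooting moves and brute-force
samples of up to ~2500 transitions; the acceptance script uses a
10,000-path chain at 12,000 K, a 2500-shot chain and a 500-transition
brute-force run at $T = E_a/3k_B \approx 4210$ K.  These sizes keep every
Monte-Carlo estimate's sampling error well inside the tolerances being
asserted while completing in minutes on one CPU.  All stochastic draws go
through R's seeded RNG (the compiled core is deterministic), so every run
is bit-reproducible from its seed, and archives written by
`write_archive()` embed the full configuration and seed in their manifest.

## What the model does and does not show

The coupled-harmonic model captures the essential physics of two
electronically coupled states — an avoided crossing, thermally activated
barrier crossing, upper-state trapping, frustrated hops — and it makes
every reference quantity computable to high statistical precision.  It
does not probe multidimensional effects (a coupling *vector*, seam
geometry, energy flow among bath modes), multi-state manifolds, or
decoherence corrections, and the efficiency ratios measured here transfer
to molecular systems only qualitatively.  Passing tests on this model
therefore validate the algorithmic machinery (reversibility, detailed
balance, ensemble correctness), not chemical accuracy for any particular
molecule.
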