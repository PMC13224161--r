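# natps

Nonadiabatic transition path sampling: deterministic, time-reversible
surface hopping (MASH) combined with trajectory-space Monte Carlo (TPS),
for harvesting rare reactive events that involve electronic transitions.

## The problem

Many photochemical processes — electron transfer, predissociation,
intersystem crossing — are *kinetic rare events*: the nonadiabatic step
itself is ultrafast, but the waiting time before it happens can exceed any
affordable brute-force simulation.  Transition path sampling solves the
analogous problem in ground-state chemistry by running Monte Carlo in the
space of reactive trajectories, but it requires dynamics that are
deterministic, time reversible, volume preserving and in detailed balance
with a stationary distribution.  Conventional surface hopping (FSSH) is
stochastic and breaks these conditions.

The mapping approach to surface hopping (MASH) does not.  The two-level
electronic state

```
|Psi> = c_ |psi_> + c+ |psi+>
```

is mapped to a unit spin on the Bloch sphere,

```
Sx = 2 Re(c+* c_),   Sy = 2 Im(c+* c_),   Sz = |c+|^2 - |c_|^2,
```

and the nuclei move on the adiabatic surface selected by `sign(Sz)`, with
the energy function

```
E(q, p, S) = p^2/2m + Vbar(q) + Vz(q) sign(Sz),
```

where `Vbar` is the mean of the two adiabatic surfaces and `2 Vz` their
gap.  When `Sz` crosses zero the active surface changes and the momentum
along the nonadiabatic coupling is rescaled to conserve `E` (or reflected,
if an upward hop has insufficient kinetic energy).  With hops located
*inside* the step by a root search, the integrator is exactly
time-reversible, so two-sided shooting moves are valid and the canonical
path ensemble

```
P_AB[X] ∝ H_AB[X] * rho(Gamma_0) * prod_i P(Gamma_i -> Gamma_i+1)
```

(`H_AB = 1` iff the path starts in basin A, ends in basin B and touches
neither in between) can be sampled with the Metropolis rule
`P_acc = h_A h_B min(1, L_old/L_new)` after an Uhlenbeck–Ornstein velocity
perturbation `v' = alpha v + sqrt(1 - alpha^2) dv`.

The package implements this machinery on a one-dimensional avoided-crossing
model of two displaced harmonic diabats (`H11 = eps((q-x0)/x0)^2`,
`H22 = eps((q+x0)/x0)^2`, `H12 = Vc`, hydrogen-atom mass), in atomic units
throughout, together with equilibrium (brute-force) sampling of the same
transitions and the full set of ensemble observables: transition times and
their chain autocorrelation, hop positions and coherence angles,
state-resolved path densities, and sampling-efficiency ratios.

## A worked example

```r
library(natps)
set.seed(42)

model <- two_state_model()        # eps = 0.05 Ha, x0 = 1 bohr, Vc = 0.2 eps
barrier_height(model) / kB_hartree
#> [1] 12631       # the barrier expressed as a temperature (K)

cfg  <- tps_config(temperature = 12000, n_paths = 2000)
path <- make_initial_path(model, config = cfg)
path
#> MASH trajectory: 104 points, dt = 5 a.t.u., span 515 a.t.u.
#>   hops: 2 (0 frustrated); status: reactive

ens <- run_tps(path, config = cfg, model = model)
summary(ens)
#> NATPS ensemble at 12000 K: 2000 MC steps (300 burn-in), acceptance 0.539
#>   <tau> = 342.0 a.t.u. (sd 181.6); decorrelation length 7 MC steps
#>   paths with >=2 hops: 31.1%; mean hop position -0.0136 bohr
#>   efficiency ratio: 158.3 steps per MC sample (293.4 per accepted path)
```

Reading the output: at 12,000 K (thermal energy comparable to the
barrier), the chain mixes quickly — roughly one statistically independent
reactive path every 7 shooting moves — and about a third of the sampled
paths are nonadiabatic, i.e. they visit the upper adiabat through at least
one up/down hop pair before connecting the reactant basin
(`q < -0.8`, lower state) to the product basin (`q > 0.8`, lower state).
The mean hop position sits at the crossing seam `q = 0`, where the gap is
minimal and the coupling strongest.  `plot(ens)` shows the right-skewed,
bimodal transition-time histogram with the nonadiabatic subpopulation
highlighted; `path_density(ens)` gives the state-resolved occupancy.

The same transitions can be harvested without importance sampling:

```r
bf <- brute_force_run(model, thermal_spec(12000),
                      total_steps_budget = 1e6, trajectory_length = 5000)
efficiency_ratio(bf$steps_used, length(bf$segments))
```

which costs thousands of integration steps per transition path instead of
~150, and verifies (two-sample KS test on transition times via
`compare_transition_times`) that TPS samples the unbiased transition-path
ensemble.

A thin command-line front end with `run-tps`, `brute-force`, `anneal`,
`sweep-coupling` and `analyze` subcommands is installed at
`inst/scripts/natps`; runs are written as self-describing plain-text
archives (`write_archive`/`read_archive`) with a YAML manifest recording
model constants, configuration and seeds, so any archive is reproducible
bit-for-bit from its manifest.

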