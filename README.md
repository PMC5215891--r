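# wormFAS

Simulation and analysis of distributed focal-axonal-swelling (FAS) injury
on the *C. elegans* somatic connectome.

Neurodegenerative disease and traumatic brain injury both leave axons
dotted with focal swellings. In *C. elegans* — the only organism with a
fully mapped wiring diagram — the behavioural cost of such damage can be
studied end to end: simulate the nervous system, injure it, and read the
deficit off the dynamics. This package implements that workflow for
computational neuroscientists:

- **Network dynamics.** Each neuron is a single-compartment passive
  membrane, `C dV_i/dt = -Gc (V_i - E_cell) - I_gap - I_syn + I_ext`,
  with ohmic gap junctions `I_gap,i = Σ_j Gg_ij (V_i - V_j)` and graded
  chemical synapses `I_syn,i = Σ_j Gs_ij s_j (V_i - E_j)`, where the
  synaptic activity obeys `ds_i/dt = ar φ(V_i)(1-s_i) - ad s_i` with a
  sigmoidal activation `φ`. Conductances are `g` times the gap/synapse
  counts of the wiring tables. Integration is forward Euler
  (`dt = 1e-4 s`) in compiled code. Activation thresholds are set so the
  zero-input network rests at a self-consistent equilibrium.
- **Injury model.** A swelling inflates a neuron's membrane area, so its
  capacitance and leak scale by `1 + μ·m_i`; equivalently the coupling
  currents are divided by that factor. Per-neuron swellings `m_i` are
  drawn from an empirical histogram and L2-normalised (`‖m‖₂ = 1`); `μ`
  is the global injury amplitude, with `μ = 0` the healthy network. The
  stimulated input pair is never injured.
- **Behavioural readout.** Constant stimulation of the input (PLM) pair
  drives a limit cycle in the forward-motion motorneurons. The cycle
  lives on the plane of the two leading SVD modes of the motorneuron
  voltage snapshots; injury deforms it and, at a critical amplitude `μ*`
  (found by bisection), collapses it to a fixed point — read as
  paralysis. Deformation is quantified by the phase-aligned Procrustes
  distance `PD = min_{b,R,c} ‖S_B - b·S_A·R + c‖²` between injured and
  healthy cycle shapes, with the optimal scaling and the centroid
  displacement reported alongside.
- **Outcome classification.** Collapse endpoints split into upper/lower
  classes along the endpoint cloud's principal axis; deterministic CART
  trees (Gini impurity, midpoint thresholds, minimum leaf size) predict
  the class from the injury vector or from normalised PD-curve shapes,
  with 10-fold cross-validation and shuffled-label baselines.

Synthetic fixtures (random toy connectomes, a frozen oscillator motif,
analytic plane trajectories, planted-structure injury ensembles) make
every stage runnable and testable without any external data.

## Worked example

```r
library(wormFAS)

cx <- oscillatorMotif()          # bundled 7-neuron network with a limit cycle
params <- attr(cx, "params")
rest <- restingState(cx, params) # self-consistent thresholds + rest state
Iext <- c(IN1 = 2e4, IN2 = 2e4)  # constant drive to the input pair

traj  <- simulateNetwork(cx, rest$params, Iext = Iext, T = 25, init = rest$state)
plane <- computePlane(traj)
plane
#> NeuralPlane over 5 neurons; two-mode energy fraction 0.9993

pt <- projectOnPlane(traj, plane)
cycleFrequency(pt, transient = 5)
#> [1] 0.5008994

inj  <- sampleInjury(syntheticSwellingDistribution(), cx, seed = 11)
prof <- findMuStar(cx, rest$params, inj, plane, Iext, init = rest$state)
prof
#> MuProfile: muStar = 0.8195801 with 15 mu samples

shape <- resampleClosedCurve(extractPeriod(pt), 200)
crv <- pdCurve(cx, rest$params, inj, prof, plane, shape, Iext, init = rest$state)
head(data.frame(mu = crv@mu, pd = crv@pd, scaling = crv@scaling,
                translation = crv@translation), 5)
#>      mu     pd scaling translation
#> 1 0.000 0.0004   1.002       0.007
#> 2 0.123 0.0007   0.909       0.275
#> 3 0.246 0.0020   0.801       0.509
#> 4 0.369 0.0027   0.677       0.701
#> 5 0.492 0.0041   0.538       0.839
```

Reading: the healthy motorneuron dynamics are essentially
two-dimensional (99.9% of the energy in two modes), cycling at 0.50 Hz.
This particular injury collapses the cycle at `μ* ≈ 0.82`; on the way
there the cycle's shape distorts (PD rising), shrinks (scaling falling
from 1) and drifts from the healthy centroid (translation rising). The
full study — ensembles of injuries, endpoint classes, classification
trees and baselines — runs through `runEnsemble()` and
`ensembleReport()`.

A thin command-line wrapper with verbs (`fixtures`, `simulate`, `plane`,
`injure`, `mustar`, `pdcurve`, `ensemble`, `report`) is at
`inst/scripts/fas-pipeline.R`.

## Layout

- `R/`, `src/` — implementation (S4 classes; compiled Euler loop)
- `tests/testthat/` — unit, property and acceptance tests
- `vignettes/fas-methods.Rmd` — the methods vignette: model, injury
  scaling, attractor criteria, Procrustes conventions, design decisions
- `inst/scripts/fas-pipeline.R` — CLI wrapper
- `scripts/acceptance.R` — headline-quantity reproduction script
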