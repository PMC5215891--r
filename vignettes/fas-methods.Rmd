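---
title: "Methods: injured connectome dynamics, shape analysis, and outcome trees"
author: "wormFAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: injured connectome dynamics, shape analysis, and outcome trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its own methods: the model and
its assumptions, the parameters that matter, the numerical choices, what
the synthetic generators do and do not emulate, and the design decisions
taken where the problem was genuinely open.

## The network model

Every neuron is a single, isopotential compartment with a passive
membrane. For neuron $i$,

$$C \dot V_i = -G_c (V_i - E_{cell}) - I^{gap}_i(\vec V) - I^{syn}_i(\vec V) + I^{ext}_i,$$

with gap junctions treated as ohmic resistances,
$I^{gap}_i = \sum_j G^g_{ij}(V_i - V_j)$, and graded chemical synapses
$I^{syn}_i = \sum_j G^s_{ij}\, s_j (V_i - E_j)$, where $E_j$ is the
reversal potential of the *sender* ($0$ mV excitatory, $-45$ mV
inhibitory) and the synaptic activity obeys

$$\dot s_i = a_r\, \phi(V_i)\,(1 - s_i) - a_d\, s_i,
  \qquad \phi(v) = \frac{1}{1 + e^{-\beta (v - V_{th})}}.$$

All neurons are identical except for their wiring and polarity.
Conductance matrices are the connection-count matrices times a single
per-connection conductivity $g$: `Gg = g * Ng`, `Gs = g * Ns`. The
synapse-count orientation is fixed as `Ns[i, j]` = synapses from
presynaptic $j$ onto postsynaptic $i$, so the current sum above runs over
columns; the file formats document this.

Parameters, with defaults (`modelParams()`):

| parameter | meaning | default | unit |
|---|---|---|---|
| `C` | membrane capacitance | 1 | pF |
| `Gc` | membrane leak conductance | 10 | pS |
| `Ecell` | leak potential | -35 | mV |
| `g` | per-connection conductivity | 100 | pS |
| `Eexc`, `Einh` | sender reversal potentials | 0, -45 | mV |
| `beta` | activation slope | 0.125 | 1/mV |
| `ar`, `ad` | synaptic rise/decay | 1, 5 | 1/s |
| `dt` | Euler timestep | 1e-4 | s |

Units are mV / pS / pF / s throughout, so currents come out in pS·mV
("arbitrary units"); the standard stimulus to the input pair is
`2e4` in those units.

**Thresholds and the resting state.** The activation threshold $V_{th}$
is not part of the published parameter set; this package computes it
per-neuron from the zero-input equilibrium (`restingState()`): with
$V_{th}$ tied to each neuron's own equilibrium voltage, $\phi = 1/2$ at
rest, the synaptic equilibrium is $s_{eq} = a_r/2 / (a_r/2 + a_d)$, and
one linear solve yields the resting voltages, which then define
$V_{th}$. Rest is therefore exactly a fixed point, and an unconnected
neuron has $V_{th} = E_{cell}$. The construction is a documented choice
(the value can be overridden through `modelParams(Vth = ...)`), and the
default initial condition of every simulation is this resting state.

**Integration.** Explicit (forward) Euler at `dt = 1e-4` s, implemented
in compiled code; `s` is clipped to $[0, 1]$ after each step to guard
explicit-integration overshoot, the sigmoid's exponent is clamped at
$\pm 50$, and a divergence guard aborts if any $|V|$ exceeds a
configurable bound (default $10^4$ mV). Recording is decimated (default
stride 100, i.e. 1 ms samples); the full final state is retained so runs
can be continued exactly. A single-neuron Euler solution matches the
analytic exponential to first order in `dt` (tested).

## The injury model

A focal swelling inflates membrane area, hence capacitance and leak:
$C_i = C (1 + \mu m_i)$, $G^c_i = G_c (1 + \mu m_i)$. Dividing through,
the injured voltage equation divides the *coupling* currents by the
swelling factor:

$$C \dot V_i = -G_c (V_i - E_{cell}) -
  \frac{I^{gap}_i + I^{syn}_i}{1 + \mu\, m_i}.$$

At $\mu m_i = 0$ the healthy equation is recovered bit-for-bit (an IEEE
division by 1.0); as $\mu m_i \to \infty$ the neuron decouples and its
voltage decays to $E_{cell}$ at rate $G_c / C$ (both tested). Swellings
$m_i$ are drawn i.i.d. from a histogram of relative swelling magnitudes,
zeroed on the protected (stimulated) pair, and L2-normalised to
$\lVert m \rVert_2 = 1$. The identity
$\langle a_i/a_H \rangle = 1 + \mu \langle m_i \rangle$ converts a target
mean area ratio into an amplitude (`muFromMeanSwelling()`); the mean is
taken over non-protected neurons. Random assignment deliberately ignores
any spatial structure of real injuries; a per-neuron weight hook exists
for spatially-biased variants.

The package does not bundle the experimentally measured swelling
histogram. `syntheticSwellingDistribution()` is a clearly-labelled
synthetic stand-in — a discretised log-normal (meanlog 0, sdlog 0.5,
median swelling 1, right-skewed like measured FAS size distributions);
any user histogram in the same two-column format is accepted, and
analyses should record which distribution was used.

## The response plane and the deficit measures

Motorneuron voltage snapshots (after discarding a 5 s transient) form a
neurons-by-time matrix whose SVD gives the response plane: the first two
left singular vectors. Snapshots are *not* mean-centred by default (the
decomposition acts on the raw matrix; a `center` switch provides
centred PCA), and the mode sign is fixed so the largest-magnitude
component is positive. The plane is computed once, from healthy
dynamics, and reused unchanged for all injured projections. The healthy
simulation records 20 s after the transient by default.

**Attractor criteria.** On the plane, the first 5 s are ignored and
successive 5 s windows are tested:

- *fixed point*: every point of the window lies within radius 0.01 of
  the window's reference centre (the window mean by default; the final
  point behind a flag). The radius is roughly three orders of magnitude
  below a healthy cycle radius, so very small cycles are deliberately
  read as fixed points.
- *periodic*: the trajectory leaves a disc of the same radius centred on
  the window's final point — a point *on* the trajectory, which is what
  makes re-entry well defined — and re-enters it at least three times at
  near-constant intervals (interval CV < 0.2). Passages are detected
  against trajectory *segments*, so a coarsely sampled cycle cannot step
  over the disc. In addition the excursion amplitude between re-entries
  must be stationary (final excursion ≥ 0.9 of the maximum): a slowly
  contracting spiral re-enters at constant intervals too, and the
  stationarity guard defers judgement until the transient has died,
  trading compute for specificity.

If neither criterion holds the simulation is extended window by window
(continuing exactly from the stored final state) up to a cap, then an
"undetermined" error with diagnostics is raised; ensemble code records
such amplitudes as flagged gaps rather than aborting.

**Collapse amplitude.** `findMuStar()` verifies the healthy dynamics are
periodic, finds a fixed-point upper bound by doubling, and bisects to a
relative bracket width of $10^{-3}$ — a balance between unreported
published precision and simulation cost. The endpoint is recorded as the
trailing-window mean of the plane projection at the fixed-point bracket
end. Amplitude sampling follows the 5 + 10 schedule: five points spaced
through $(0, 0.9\mu^*)$ and ten through $(0.9\mu^*, \mu^*)$, endpoints
excluded.

**Procrustes analysis.** One cycle period is cut between consecutive
same-direction Poincaré crossings through the cycle centroid (the
section carries a hysteresis band, 0.3 of the vertical spread, so noisy
trajectories do not generate spurious crossings; `cycleFrequency()`
additionally smooths with a centred 1%-of-record running mean). The
period is resampled to $N = 200$ points by periodic cubic splines at
uniform parameter spacing ($N \ge 100$ changes PD by well under 1% on
smooth cycles). The Procrustes solution is closed-form: centre both
shapes, take the SVD of the cross-covariance for the optimal rotation
(determinant +1 — reflections excluded), then the optimal scale and
translation. The reported dissimilarity is the residual sum of squares
normalised by the centred sum of squares — the standardised Procrustes
dissimilarity, which is symmetric in the two shapes — alongside the raw
residual. Because reversing a cycle's traversal direction is a
correspondence change rather than a rotation, phase alignment searches
all $N$ cyclic shifts *and* both directions by default (single direction
behind a flag). The scale factor `b` is the factor applied to the
healthy shape to match the injured one, so a shrinking cycle gives
`b < 1`; translation is reported as the displacement of the injured
cycle centroid from the *healthy* centroid (the healthy cycle is not
centred on the plane origin in general, and this convention makes the
healthy-vs-healthy translation exactly zero).

**Curve normalisation.** For class-averaged curves, each curve's
amplitude axis is rescaled to $[0,1]$ by its maximum sampled amplitude
and PD values are rescaled to maximum 1; scaling and translation curves
keep their natural units, since their raw monotone trends are the object
of interest. Curves are spline-interpolated onto a common grid and
averaged pointwise. The same normalised-PD grid (default 20 points) is
the feature vector for curve-shape classification, making features
invariant to a rescaling of $\mu^*$.

## Endpoint classes and classification trees

Collapse endpoints are split along the leading principal mode of the
endpoint cloud, labelling projections $\ge -0.01$ as "upper". Whether
the cloud should be mean-centred before the SVD is ambiguous (the
printed threshold suggests a near-centred cloud); the default is
mean-centred with the threshold exposed, and the raw-projection variant
sits behind `center = FALSE`.

Trees are deterministic CART: greedy binary splits on single features
maximising Gini impurity decrease, candidate thresholds at midpoints
between consecutive sorted unique values, splits admissible only when
both children hold at least `minLeaf` samples, and ties broken by lowest
feature index then lowest threshold — so a fitted tree is a pure
function of the data. Cross-validation uses uniform random (seeded, not
stratified) fold assignment with 10 folds, reporting the overall
held-out misclassification fraction; shuffled-label baselines repeat the
procedure on permuted labels (default 100 trials) and report mean ± sd.
Feature importance is the total sample-weighted impurity decrease per
feature. The full-study configuration fixes `minLeaf = 40`, chosen by a
leaf-size sweep; small synthetic studies scale it down with the ensemble
size. The tree machinery is authored in the package (the deterministic
conventions above are part of the contract); `rpart` serves only as an
independent cross-check in the tests.

## Behavioural mapping

The healthy cycle is affinely calibrated onto the unit circle at matched
uniform phase (`calibrateCircleMap()`); the calibration is fitted once
and reused for all injured trajectories, so a collapsed fixed point maps
to a constant posture. The relative rotation between the neural plane
and the behavioural plane is unknown in principle; the default resolves
the ambiguity by anchoring the target phase at the first point's angular
position (so a unit circle calibrates to the identity), and a
configurable rotation remains available. The fit includes an offset term
by default (pure-linear behind a flag). Eigenworm bases are
user-supplied; `syntheticEigenwormBasis()` is a sinusoidal,
non-biological stand-in for demos. Note that PD is similarity-invariant
but not affine-invariant, so all shape statistics are computed in the
neural plane, never after the behavioural mapping (tested).

## Synthetic fixtures: what they do and do not show

`syntheticConnectome()` emulates the *format and invariants* of real
wiring tables (symmetric gap counts, directed synapse counts, polarity,
input/motor groups) at small n — not their topology or degree structure.

`oscillatorMotif()` is the frozen test network: a five-neuron
heterogeneous ring (three inhibitory members giving a delayed negative
feedback loop) touched by a weak synapse from a gap-coupled input pair.
Its frozen constants include a steeper activation slope
($\beta = 1$/mV) than the connectome-wide default: a systematic
linearised-gain analysis around the rest-anchored operating point shows
that with $\beta = 0.125$/mV every single link's small-signal gain is
bounded well below one, so *no* compact circuit can cross the
oscillatory (Hopf) threshold — the full-scale network's limit cycle is a
collective, many-loop effect. The fixture therefore realises the same
limit-cycle phenomenology (stable 0.50 Hz orbit, two-mode plane with
99.9% energy, collapse to a fixed point under rising injury) in seven
neurons by sharpening the activation; every governing equation is
otherwise identical. Consequently, tests passing on the motif exercise
the machinery — integration, plane, bisection, shape analysis — but say
nothing about the biological network's parameter regime.

`plantedEnsemble()` generates injury matrices with labels that depend
only on two designated driver neurons through an axis-aligned rule
(upper iff either driver exceeds its 0.7-quantile threshold, with
optional Gaussian label noise). The rule is expressible by a depth-two
tree, so at zero noise cross-validation error approaches zero and the
drivers are recoverable — a positive control for the classification
stage with a computable null. Real injury-to-outcome structure is of
course not axis-aligned; the planted ensemble checks the estimator, not
the biology.

`analyticTrajectory()` supplies closed-form circles, ellipses, spirals
and fixed points with known period and endpoint for the attractor and
shape machinery.

## Pipeline, seeds, and problem sizes

`runEnsemble()` executes resting state → healthy plane → per-injury
($\mu^*$ bisection → schedule → PD curve → endpoint) → endpoint split →
trees (injury features and PD-shape features) → shuffled baselines,
checkpointing each injury as JSON keyed by a config hash so interrupted
runs resume bit-identically. Seeds follow a counter scheme
(`childSeed(master, index)`), so enlarging an ensemble never perturbs
earlier injuries; per-injury work is independent and order-free. The
frequency-reduction statistic is computed per injury as the mean of
$1 - f(\mu)/f(0)$ over periodic samples in $(0.9\mu^*, \mu^*)$, then
averaged over injuries (the exact averaging order is a documented choice).

The shipped test-and-demonstration sizes — 25 s healthy runs, 20 s
per-classification runs, ensembles of 3 motif injuries and 50 planted
injuries, 100-trial baselines — were chosen so the whole suite and the
reproduction script each complete in minutes on a single CPU while still
exercising every stage; the full-connectome configuration
(`inst/extdata/ensemble-config-varshney.json`, 279 neurons × 1,447
injuries) runs for hours and requires the external wiring tables.

## Known limitations

- Neurons are passive and identical; bistable or spiking neuron classes
  are out of scope, as are muscles, body mechanics and environmental
  feedback — so no speed prediction is attempted.
- The attractor criteria can, by design, read very small cycles as fixed
  points, and extremely slow transients may exhaust the window cap and
  be flagged undetermined rather than classified.
- $V_{th}$ is a construction, not a measured value; results near the
  oscillatory threshold can be sensitive to it.
- The behavioural mapping is an artificial calibration; its rotation is
  unidentifiable from within the model.
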