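---
title: "Hierarchical suppression and the grooming sequence: model, parameters and design choices"
author: "groomSim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical suppression and the grooming sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groomSim)
```

## The problem and the model

A fly coated in dust receives simultaneous sensory drive to many
body-cleaning motor programs, yet grooms in a reliable anterior-to-posterior
order with frequent returns to earlier body parts and constant interleaving of
leg rubbing. `groomSim` implements the parallel account of this sequence:
all modules are driven at once, a hierarchy shapes their activation, and a
winner-take-all stage executes exactly one behavior per timestep.

The state is a dust vector $d \in [0, d_{\max}]^N$, initialised as
$d_k = b + r_k$ with $r_k \sim U(0, \eta)$ ($b = 0.9$, $\eta = 0.1$ by
default, so $d_{\max} = 1$). Activation at each iteration is

* flat: $a = d$;
* sensory gain (SGM): $a = d \circ w^s$, $w^s$ strictly decreasing;
* unidirectional inhibition (UIM): $a = dW$, where $W$ has unit diagonal and
  the constant $w = -0.5$ on its strict upper triangle, so module $k$
  inhibits every module $j > k$ in proportion to the dust on $k$'s body part.

The winner is $m_a = \arg\max a$ (ties to the lowest index, i.e. the
hierarchically superior module) and $d_{m_a} \leftarrow \max(d_{m_a} - d_r,
0)$. Constitutive activation of a module — the in-silico analogue of forcing
its sensory channel on — holds its dust at the clamp value after every
iteration. With legs enabled, two leg pairs join the competition: each
body-cleaning iteration adds `legIncrement` of dust to the pair assigned to
the winner (front pair for module indices at or below `anteriorBoundary`,
hind pair otherwise), leg activation equals leg dust, and a pair rubs (and
sheds `legDustRemoval`) exactly when its activation is at or above the
stationary threshold, strictly above every body module, and strictly above
the other pair. The winner-take-all stage itself is an argmax, not an
explicit all-to-all inhibitory network; simulating that circuitry is outside
the model's scope.

## Parameters, defaults, and why

| parameter | default | units / meaning |
|---|---|---|
| `nModules` | 5 (4 with legs) | number of body-cleaning modules, hierarchy order eye > antenna > abdomen > wing > thorax |
| `dustBase`, `dustNoise` | 0.9, 0.1 | initial dust $b + U(0,\eta)$, dimensionless fraction of maximal dust |
| `dustRemoval` ($d_r$) | 0.05 | dust removed per winning iteration; 0.05 gives roughly 20 cleaning iterations per body part and run lengths of a few hundred timesteps |
| `sensoryWeights` | `seq(2, 1, length.out = N)` (SGM) | chosen so adjacent weight gaps dominate the 0.1-wide initial noise, making the first-selection order deterministic |
| `inhibitionWeight` | −0.5 (UIM) | upper-triangle entry of $W$ |
| `clampValue` | `dustBase + dustNoise` | dust level held on constitutively activated modules. It is a separate field so the "activation without dust" scenario (`dustBase = 0` elsewhere) can still clamp at maximum |
| `legIncrement`, `legThreshold`, `legDustRemoval` | 0.05, 0.8, 0.05 | free parameters of the leg extension; the published description fixes only their roles, not values |
| `anteriorBoundary` | 3 | winners with index ≤ 3 dirty the front pair, others the hind pair, also when only 4 body modules run |
| `nIterations` | 300 | fixed horizon; no convergence criterion is part of the model. `firstClearIteration()` reports when all unclamped dust is gone |

One integer seed drives a single random stream; draws occur in a documented
order (body modules 1..N, then the two leg pairs), so runs are bit-for-bit
reproducible and `initialDust` / `initialLegDust` overrides skip exactly the
corresponding draws.

### The inhibition recurrence

The UIM update is implemented as **stateless**: activation is recomputed from
the *current* dust each iteration, $a^{(i)} = d^{(i)} W$. An alternative,
**literal** reading iterates $a^{(i+1)} = a^{(i)} W$ with dust entering only
through the initial condition. The literal recurrence cannot produce a
grooming sequence: because $W$ is unitriangular, the top module's activation
is exactly constant no matter how much it cleans, and powers of $W$ diverge
polynomially with alternating signs, so activations leave the dust range
within a handful of iterations (a unit test documents both facts). Since
cleaning is supposed to lower the cleaner's own drive, stateless is the
default; `uimRecurrence = "literal"` is retained for comparison.

### Other conventions

* Noise is drawn once at initialisation; there is no per-iteration noise.
  In the flat model this initial noise alone decides the selection order.
* Dust floors at zero; activations may go negative under inhibition (no
  clamp is applied to $a$ — negative values only deepen suppression and never
  affect the argmax of the competing positive ones).
* Ties at the argmax go to the superior module. This makes the noise-free
  flat model a deterministic round-robin and, after full clearance, parks
  selection on module 1.
* With legs enabled, the leg pairs start dusted like the body modules (two
  additional uniform draws). The modelled fly is coated all over, and rubbing
  is observed from the earliest cleaning bouts; starting the legs clean would
  instead require ~16 body-cleaning iterations before the front pair could
  reach the 0.8 threshold, suppressing the early body/leg alternation the
  extension exists to produce.
* Module labels map indices 1..N to eye, antenna, abdomen, wing, thorax;
  iterations and module indices are 1-based everywhere, including CSV output.

## Behaviors the simulator reproduces

```{r scenarios}
names(scenarioConfigs())
```

The six canonical scenarios are: `flat` (equal sensitivities, no inhibition:
interleaved switching, equal long-run selection shares), `sensoryGain` and
`inhibition` (both hierarchy variants: first selections strictly in hierarchy
order, return cleaning as activations equalise, full clearance),
`clampClean` (a clamped module with no dust elsewhere is executed
exclusively), `clampDusty` (a clamped mid-hierarchy module under full dust:
modules below it are never selected), and `legRubbing` (four body modules
plus both leg pairs under inhibition: body/leg alternation throughout while
the body order is preserved).

Two model properties discovered while testing deserve note. First, in the
`clampDusty` scenario the modules *above* the clamp do not clean to zero:
once their dust has fallen enough that the clamped module's activation
$1 - 0.5(d_1 + d_2)$ exceeds theirs (around $d_1 \approx 0.44$), the clamped
module wins every remaining iteration and the residual dust above it is
frozen — persistent activation does not merely suppress its inferiors, it
eventually starves its superiors too. Second, return cleaning means a rub is
often followed by a *different* body module than the one preceding it;
strict body→leg→same-body cycles dominate only while one module's activation
clearly exceeds the rest (typically the top module's early epoch).

## The synthetic-data generators

`generateMarkovEthogram` emits bout sequences from a zero-diagonal,
row-stochastic chain with geometric (memoryless) bout lengths — the minimal
structure consistent with first-order transition analysis. It emulates the
bout-and-transition skeleton of scored behavior, not dwell-time
distributions, observation noise, or scoring ambiguity in real video.
`generateDustImageStack` draws each pixel independently from a probability
map; real dust patterns are spatially correlated, so tests against it
validate the averaging and counting arithmetic, not robustness to realistic
textures. `generateDecaySeries` evaluates an exponential or four-parameter
logistic decay with additive Gaussian noise clipped to $[0, 1]$; measurement
noise in real dust fractions is uncharacterised. Passing tests therefore
demonstrate correctness of the estimators on their idealised data-generating
processes, not performance on real imagery or video.

## Numerical choices

* Transition matrices count transitions between *bouts* (maximal runs) by
  default, so self-transitions are impossible and the count diagonal is zero;
  a `unit = "timestep"` mode is available. Rows with no outgoing transitions
  are all-zero and flagged, never renormalised. Row sums of populated rows
  are exact to 1e-12.
* Marginal probabilities are bout counts over total bouts (exact rational
  arithmetic up to floating point); the cohort variant averages per-subject
  fractions rather than pooling bouts.
* `fitT50` uses Levenberg–Marquardt least squares (`minpack.lm`). The
  "sigmoidal" model is the 4-parameter logistic (lower/upper asymptote,
  midpoint, slope). $t_{50}$ is defined on the *fitted* curve as the time it
  crosses half the fitted value at $t = 0$ (closed form $\ln 2 / k$ for the
  exponential); when the parametric fit fails or never crosses, a flagged
  model-free linear interpolation of the raw series is used. At the
  synthetic-study conditions used in the tests (additive noise of sd 0.05,
  8 timepoints spanning 2.5 half-lives) the median relative recovery error
  is near 5% — that is the information content of such a series, not slack
  in the fitter, and the estimator is unbiased (median recovered $t_{50}$
  within about 1%).
* The interval variant of `boutFrequency` assigns each bout to the single
  interval containing its start.
* Dust images are binary 0/1 in memory; rasters are written 8-bit with the
  0/255 convention and binarized at 0.5 on read. Stacks must match in
  dimensions exactly — registration/warping of raw photographs is out of
  scope. Dust maps additionally round-trip losslessly through CSV.
* `writeTransitionGraph` applies the display threshold (e.g. 0.05) to the
  exported edge list only; the matrix itself is never masked.

## Problem sizes in the test suite

The suite exercises the long-horizon flat-symmetry study at 10,000 iterations
by 20 seeds with $d_r = 4\times10^{-4}$ — scaled so that total initial dust
(~4.75) outlasts the horizon, keeping the competition alive for the whole
run; at the standard $d_r = 0.05$ a run clears in ~100 iterations, after
which the deterministic tie-break makes long-horizon shares meaningless.
Hierarchy ordering, clearance and return cleaning are checked across 100
seeds per variant; conservation on 200 random configurations; oracle
equivalence (an independently written straight-line single-step
implementation) on 100; transition-estimator consistency at 100/1,000/10,000
bouts over 50 seeds; and $t_{50}$ recovery over 200 noisy series.

## Known limitations

* Iterations are abstract timesteps; there is no continuous time, spiking
  dynamics, or kinematics, and no fitting of parameters to animal data.
* The leg extension's constants are free parameters; conclusions drawn from
  leg simulations should be checked for robustness to them.
* The image pipeline assumes pre-registered, same-size rasters and a
  caller-defined binarisation threshold; no colour calibration is attempted.
* Cohort-level hypothesis testing (rank tests and multiple-comparison
  corrections on animal cohorts) is deliberately out of scope.
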