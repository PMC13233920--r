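---
title: "Homeostatic regulation of a model pyloric pattern generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homeostatic regulation of a model pyloric pattern generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pyloricnet)
```

## The model

`pyloricnet` studies when *local* activity-dependent homeostatic
plasticity (ADHP) can maintain a *circuit-level* property. The test bed is
a three-neuron continuous-time recurrent neural network (CTRNN) standing
in for the pyloric central pattern generator of the crustacean
stomatogastric ganglion. The neurons are labelled LP (lateral pyloric),
PY (pyloric) and PD (pyloric dilator, which also absorbs the AB pacemaker
of the biological kernel). Each neuron is a leaky integrator

$$\tau_i \frac{dy_i}{dt} = -y_i + \sum_{j} w_{j \to i}\,\sigma(y_j + \theta_j),
\qquad \sigma(x) = \frac{1}{1 + e^{-x}},$$

with output $o_i = \sigma(y_i + \theta_i) \in (0,1)$ read as a normalized
firing rate. A circuit is specified by 15 parameters: three time constants
$\tau_i \in [0.1, 2]$ s, three biases $\theta_i \in [-16, 16]$, and nine
weights $w_{i \to j}$ (the weight bounds are not dictated by the biology;
we default to $[-16,16]$, symmetric with the biases, and record the choice
in run metadata).

## Pyloricness

A **burst** is a maximal epoch with output strictly above the threshold
0.5 (a sample exactly at threshold counts as below; boundaries are placed
by linear interpolation between samples). A rhythm in which each neuron
has exactly one burst per cycle is **pyloric** when three criteria hold
simultaneously: all neurons are silent at the LP burst onset; the PY
burst begins before the LP burst ends; and the LP burst ends before the
PY burst ends. Anchoring each cycle at the LP onset, the other five burst
boundaries can be ordered in $5! = 120$ ways (PY and PD bursts may wrap
the cycle boundary, so no permutation is unphysical), of which exactly 10
satisfy all three criteria:

```{r}
eo <- enumerate_orderings()
length(eo$all); length(eo$pyloric)
```

Circuits are scored with a staged fitness: $P_b = 0.05\,(n +
[n{=}3](c_1 + c_2 + c_3))$ over the number of bursting neurons and the
three criteria, so $P_b = 0.3$ *is* the definition of pyloric. A timing
bonus $P_t = 5 / \sum |z|$ over five z-scored timing metrics (three duty
cycles; LP and PY start phases relative to PD) rewards realistic timing;
it is only defined for pyloric rhythms, and the total is
$P = P_b + [P_b{=}0.3]\,P_t$.

### Numerical choices in the rhythm classifier

* **Cycle folding.** The period is estimated from successive upward
  threshold crossings of a reference neuron (LP first), requiring at
  least three consecutive inter-crossing intervals that agree within 1%.
  The analyzed cycle is then folded between two *actual* consecutive LP
  onsets consistent with that estimate — folding against
  `anchor + period` is fragile, because cycle-to-cycle jitter in the
  estimate can pull the next onset into the window and spuriously fail
  the one-burst-per-cycle test.
* **Ties.** Two events closer than one sample step are reported as a tie;
  the ordering is then undefined, all criteria are set false, and the
  rhythm is conservatively non-pyloric. This keeps `pyloric == (P_b == 0.3)`
  an exact equivalence.
* **Gap criterion.** The silent-gap requirement before the LP onset is
  operationalized as an instantaneous test (neither PY nor PD bursting at
  the onset, i.e. neither burst wraps the fold); a configurable minimum
  gap duration is available and defaults to 0.
* **Non-oscillatory averages** are taken over a trailing 50 s window,
  matching the grid-scan protocol below.

## ADHP

Regulated biases become slow state variables:

$$\tau_{\theta_i}\frac{d\theta_i}{dt} = \rho(\langle o_i \rangle_{s_i}),
\qquad
\rho(x) = \begin{cases} LB - x & x < LB \\ 0 & LB \le x \le UB \\
UB - x & x > UB, \end{cases}$$

where $\langle o_i \rangle_{s_i}$ is a sliding-window average of the
neuron's own output. A mechanism has four meta-parameters per regulated
bias: $LB \in [0,1]$, range width $\Delta \in [0,1]$ (with $UB$ clipped
at 1), window $s \in [0,10]$ s, and $\tau_\theta \in [100, 200]$ s —
at least fifty times every neural time constant, which enforces the
timescale separation that the whole analysis relies on. Biases are
hard-clipped to $[-16, 16]$ at every step.

Implementation decisions (the source model leaves these open):

* Slow and fast variables are co-integrated at the same fixed step; the
  bias moves $O(dt/\tau_\theta) \le 10^{-4} dt$ per step, so parameters
  are treated as frozen within each fast RK4 step and the bias advances
  by an Euler update. A separate slow solver would buy nothing at this
  accuracy.
* The sliding window is a ring buffer of output samples; during the first
  $s_i$ seconds the average is taken over the samples available
  (warm-up). $s_i = 0$ means instantaneous detection.
* During a long regulation run the integrator may stop early only when
  the system is *exactly* frozen — fast states at a fixed point and every
  regulated bias either undriven or pinned at a bound with outward drive —
  in which case the remaining trajectory is constant by construction.
* Fitness measurements during regulation (`adhp_fitness()`) freeze the
  parameters at the checkpoint and evaluate the frozen-parameter rhythm;
  the enforced 50:1 timescale separation makes the frozen rhythm a
  faithful stand-in for the live one (this is tested).
* Terminal outcomes are classified from a 2000 s trailing window of the
  bias trajectory with an endpoint tolerance of 0.05 bias units and a
  parametric-cycle threshold of 0.5. These two numbers are ours, chosen
  to separate the small-amplitude endpoint oscillations that timescale
  separation produces (endpoints are really small parametric limit
  cycles) from the large bifurcation-driven cycles; they are not claimed
  from data.

## Evolutionary optimization

Both circuits and mechanisms are optimized with a steady-state
"microbial" GA: pick two individuals at random, mutate a copy of the
fitter one over the other. One generation is `pop_size` tournaments; the
best individual is never lost, so best-of-population fitness is monotone.
Genomes live in $[0,1]^n$ and map affinely to parameter ranges. Mutation
is per-gene Gaussian ($\sigma = 0.05$ in genome space, reflected at the
bounds) with no crossover — the source describes only "copied and
randomly mutated / removed", so the operator details are our choice,
made for reproducibility and simplicity. Circuit fitness uses $P_b$
(order-only mode) or $P$ (timing mode); mechanism fitness is

$$A = \tfrac{1}{18}\sum_{i=1}^{9}\big([P + [P_b{=}0.3]\,\alpha]_{t=2500}
 + [P + [P_b{=}0.3]\,\alpha]_{t=5000}\big), \qquad \alpha = 25,$$

over a $\{-9,0,9\}^2$ grid of absolute bias perturbations with 250 s of
pre-regulation equilibration. Full-protocol mechanism evolution is
expensive (thousands of multi-thousand-second simulations); the test
suite exercises the machinery end to end at drastically reduced
population/checkpoint settings and relies on the certified fixture suite
for full-budget products.

## The predictive framework

Because regulation is slow, its net effect over one rhythm cycle is the
cycle average of $\rho(o_i)$; for a zero-width target range with value
$B_i$ this reduces to $B_i - \bar o_i$. Homeostatic nullclines in the
regulated-bias subspace therefore sit where the target equals the
cycle-averaged output, and an intersection of nullclines is stable along
axis $i$ when $\partial \bar o_i / \partial \theta_i > 0$ (flow positive
below the nullcline, negative above — the "intended" effect of raising a
bias). The hard bias bounds act as extra nullclines, stable wherever the
flow points outward. `scan_subspace()` maps $\bar o$, pyloric status and
dynamics class over a bias grid; `predict_endpoints()` intersects stable
nullcline branches (including boundary segments) and labels the
mechanism `reliable` / `mixed` / `fail` / `no-steady-state`.

On the stability sign: the source text is internally inconsistent for its
third example circuit (it names a *positive* $d\bar o_{LP}/d\theta_{LP}$
while describing bias increases that "paradoxically lower" activity); we
follow the flow-arrangement definition above, under which the paradoxical
(unstable) case is $\partial \bar o_i/\partial \theta_i < 0$.

Two further numerical choices matter here. Cells that neither oscillate
detectably nor settle to a fixed point within the per-cell budget are
recorded as *unclassified*: their trailing-window averages are not
asymptotic quantities, so their flow is treated as unknown (`NA`) and
they are excluded from binning — otherwise transients generate phantom
nullcline crossings. And when `predict_vs_simulate()` assigns a
per-target category, it does so from average-space occupancy
(`predict_category()`): the stable cells whose cycle averages match the
target at the binning resolution are collected and classified by pyloric
status. This is how the subspace maps are read in the source analysis,
and it is robust where block-based intersection detection is not (near
sharp features, two nearly parallel nullclines produce chains of spurious
intersections; we verified by direct simulation that such alleged
endpoints are immediately abandoned). The geometric
`predict_endpoints()` report is still what supplies the anomaly flags.

**Separability** rounds each cell's regulated-neuron averages to 0.01 and
asks whether some bin is occupied exclusively by pyloric, stable cells.
If yes, a zero-range mechanism targeting that bin destabilizes every
non-pyloric configuration and the circuit is fully regulatable; if stable
pyloric bins exist but all are shared, regulation is at best
perturbation-dependent; if none exists, local ADHP cannot even partially
regulate the circuit. The same binning drives the generalization analysis
across circuit pairs and extends unchanged to three regulated biases.

Known limitations, flagged rather than predicted:

* **Flip-flop parametric cycles.** Where two fixed-point branches
  adjacent along a regulated axis straddle the target with the unstable
  flow arrangement, regulation can bounce between branches across a
  bistable band and settle into a large parametric limit cycle far from
  any nullcline. Such cells raise a `flip_flop_risk` flag; the framework
  does not attempt to predict the resulting cycle.
* **Boundary pinning.** Endpoints manufactured by the bias bounds are
  genuine but depend on the imposed range; they raise
  `boundary_dependence`.
* **Wide target ranges.** For oscillatory cells whose mean lies inside
  $[LB, UB]$ the averaged drive cannot be recovered from the stored mean
  alone; those flows are reported as ambiguous (`NA`) and wide-range
  predictions are correspondingly conservative. A wider range can never
  create more oscillatory endpoints than a narrow one — it can only
  additionally capture fixed points inside its dead zone.
* **Multistability.** One fast initial condition ($y = 0$) is used per
  scan cell; rare multistable cells resolve to the limit set reached from
  it. The limit-set index is retained in the design for future
  multi-start scans.

## The fixture suite: what a green test establishes

The spec-level claims about *databases* of evolved circuits (how many of
100 are regulatable, generalization percentages, specific cycle periods)
depend on unpublished random seeds and are not reproduction targets.
Instead, the package ships a small certified fixture suite
(`fixture_suite()`): a zero-weight circuit with closed-form behaviour,
square-wave generators for all ten pyloric orderings, and pyloric
oscillators found by seeded GA runs realizing each regulatability
archetype — fully-regulatable (separable), partially-regulatable
(2D-inseparable), and unregulatable-by-instability. Each record stores
its GA recipe (seed, population, generations) and is re-certified by the
test suite from the stored parameters. A green suite therefore
establishes that the *mechanisms* of the model behave as described on
representative instances — not that any database-level frequency from
the source is reproduced.

Synthetic timing statistics used in tests set the duty-cycle means to the
reported experimental values (0.264, 0.348, 0.385 for LP/PY/PD) but
invent round standard deviations and phase statistics, because the full
experimental table is not reproduced in the source text; they are
labelled synthetic wherever they appear and are required, not defaulted,
in user-facing timing fitness.

## Scaling choices

Grid scans default to a 0.25 bias step in 2D desk-scale runs (the source
used 0.01 at cluster scale); certification scans in the tests use 0.5–1.
The prediction-versus-simulation comparison in the acceptance tests uses
an 11×11 target lattice with 25 perturbations and 50,000 s of regulation
per probe at a coarsened integration step (0.05 s, valid because the
fixture's smallest time constant exceeds 0.5 s); early exit on exactly
frozen states keeps the wall time inside the test budget without
changing any trajectory.
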