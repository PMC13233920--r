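# pyloricnet

Tools for asking when *local* homeostatic plasticity can maintain a
*circuit-level* property. The model system is a three-neuron
continuous-time recurrent neural network (CTRNN) standing in for the
pyloric central pattern generator of the crustacean stomatogastric
ganglion — a circuit whose neurons (LP, PY, PD) must burst in a specific
triphasic order, and which famously recovers that order after
perturbation through activity-dependent homeostatic plasticity (ADHP)
even though each neuron only senses its own average activity.

The package provides, as a tested library plus a thin CLI:

* **CTRNN core** — fixed-step RK4 (and Euler) integration of
  `tau_i dy_i/dt = -y_i + sum_j w_{j->i} sigma(y_j + theta_j)`, with
  outputs `o_i = sigma(y_i + theta_i)` read as firing rates.
* **Rhythm analysis** — burst parsing at the 0.5 output threshold,
  period detection, LP-anchored cycle folding, classification of the
  `5! = 120` burst-event orderings and the 10 that satisfy the pyloric
  criteria, duty cycles, phases, cycle-averaged outputs.
* **Fitness** — the staged pyloricness score
  `P_b = 0.05 (n + [n=3](c_gap + c_PYS<LPE + c_LPE<PYE))`, the timing
  bonus `P_t = 5 / sum |z|`, the total `P`, and the ADHP recovery
  fitness `A` (mean of `P + [pyloric]*25` over a 3x3 perturbation grid
  at two regulation checkpoints).
* **ADHP** — slow regulation of neuronal biases,
  `tau_theta dtheta/dt = rho(<o>_s)`, with a piecewise-linear drive
  toward a target activity range, sliding-window activity detection,
  hard bias bounds at ±16, and outcome classification (interior /
  boundary endpoints, parametric limit cycles).
* **Evolution** — a reproducible microbial GA for circuits (against
  `P_b` or `P`) and for ADHP mechanisms (against `A`).
* **Prediction** — grid scans of the ADHP-accessible bias subspace,
  homeostatic nullclines (`target = cycle-averaged output` for
  zero-range mechanisms), stable-endpoint prediction, separability
  verdicts at 0.01 activity-bin resolution, generalization across
  circuit pairs, and predicted-versus-simulated comparison tables.

## Worked example

```r
library(pyloricnet)

# the certified separable fixture circuit shipped with the package
f <- suite <- fixture_suite()
circ <- Filter(function(x) x$id == "fully-regulatable", suite)[[1]]$circuit

# 1. its rhythm
desc <- analyze_rhythm(integrate_ctrnn(circ, config = sim_config()))
desc
#> <rhythm_descriptor>
#>   period   : 5.361 s
#>   bursting : 3 of 3
#>   ordering : LP_S PY_S LP_E PD_S PY_E PD_E
#>   criteria : gap=TRUE  PYS_before_LPE=TRUE  LPE_before_PYE=TRUE
#>   pyloric  : TRUE
#>   duty     : LP=0.357  PY=0.284  PD=0.203
#>   obar     : LP=0.360  PY=0.293  PD=0.208
```

The circuit is pyloric: all three neurons burst once per cycle in the
LP–PY–PD order (here a variant where the PD burst starts before the PY
burst ends, one of the 10 admissible orderings), so its base fitness is
`P_b = 0.3`.

```r
# 2. regulate it back after a perturbation: target its own averages
ob <- cycle_average(integrate_ctrnn(circ, config = sim_config()))
mech <- zero_range_mechanism(c(LP = ob[["LP"]], PD = ob[["PD"]]))
run <- simulate_with_adhp(circ, mech, perturb = c(LP = -9, PD = 9),
                          duration = 50000, config = sim_config())
run$outcome
#> <outcome_record>  interior endpoint
#>   terminal biases: LP=0.418  PD=-5.185
#>   pyloric at end: TRUE
```

Starting from biases perturbed to (−9, +9), the slow bias dynamics carry
the circuit back to an interior endpoint near its evolved biases
(0.440, −5.250), where each neuron's cycle-averaged output equals its
target — and the rhythm there is pyloric again.

```r
# 3. why it works: the subspace map
scan <- scan_subspace(circ, c("LP", "PD"), step = 0.5)
separability(scan)$verdict
#> [1] "fully-regulatable"
```

Some pair of average activity values occurs *only* among pyloric
configurations of this bias plane, so a mechanism targeting it cannot be
fooled: activity is a reliable proxy for burst order here. Other fixture
circuits in the suite realize the two failure modes (pyloric averages
inseparable from non-pyloric ones; pyloric cells homeostatically
unstable).

(Numbers above are what the shipped fixture prints; re-running the code
reproduces them exactly.)

## CLI

```sh
Rscript -e 'pyloricnet::cli_main()' analyze --circuit circ.json --record 200
Rscript -e 'pyloricnet::cli_main()' recover --circuit circ.json \
    --mechanism mech.json --perturb -9,9 --duration 20000 --out traj.csv
Rscript -e 'pyloricnet::cli_main()' scan --circuit circ.json --step 0.5 \
    --out scan.json
```

## Layout

* `R/`, `src/ctrnn.cpp` — library code; the integrators, the coupled
  fast/slow ADHP stepper and the grid scanner are compiled.
* `vignettes/homeostatic-regulation.Rmd` — the model, the predictive
  framework, numerical choices, and what the fixture suite does and does
  not establish.
* `inst/extdata/fixture_circuits.json` — certified fixture circuits with
  their GA recipes.
* `tests/testthat/` — unit, property and acceptance tests.
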