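# Shared fixtures built in code. Everything is deterministic.

# analytic circuit: all weights zero, so y* = 0 and o_i = sigma(theta_i)
zero_weight_circuit <- function(tau = 1, theta = 0) {
  circuit_params(tau = tau, theta = theta, w = matrix(0, 3, 3))
}

# a hand-built two-neuron limit-cycle oscillator (third neuron driven but
# silent); period is about 29 s
helper_oscillator <- function() {
  circuit_params(
    tau = c(LP = 1, PY = 1, PD = 1),
    theta = c(LP = -2.75, PY = -1.75, PD = 0),
    w = matrix(c(4.5, -1, 1,
                 1, 4.5, 0,
                 0, 0, 0), 3, 3, byrow = TRUE))
}

osc_config <- function(record = 200, dt = 0.01) {
  sim_config(dt = dt, transient = 50, record = record)
}

# synthetic timing statistics for tests (duty-cycle means are the reported
# experimental values; SDs and phase statistics are invented test values,
# NOT experimental data)
synthetic_timing_stats <- function() {
  timing_stats(duty_mean = c(LP = 0.264, PY = 0.348, PD = 0.385),
               duty_sd = c(LP = 0.05, PY = 0.05, PD = 0.05),
               phase_mean = c(LP = 0.34, PY = 0.54),
               phase_sd = c(LP = 0.05, PY = 0.05))
}

# certified fixture circuits shipped with the package
suite <- NULL
get_suite <- function() {
  if (is.null(suite)) suite <<- fixture_suite()
  suite
}
suite_circuit <- function(id) {
  s <- get_suite()
  for (f in s) if (identical(f$id, id)) return(f)
  stop("fixture ", id, " not in suite")
}

# square-wave rhythm realizing given duty cycles / phases (PD-anchored),
# as an LP_S-anchored phase map
phases_from_timing <- function(duty, phase_pd_anchored) {
  # phase_pd_anchored: burst-start delays from PD start (PD = 0)
  starts <- phase_pd_anchored
  ends <- starts + duty
  # shift so that LP_S is at 0
  sh <- function(x) (x - starts[["LP"]]) %% 1
  c(LP_S = sh(starts[["LP"]]), LP_E = sh(ends[["LP"]]),
    PY_S = sh(starts[["PY"]]), PY_E = sh(ends[["PY"]]),
    PD_S = sh(starts[["PD"]]), PD_E = sh(ends[["PD"]]))
}
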