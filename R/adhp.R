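# Activity-dependent homeostatic plasticity: slow regulation of neuronal
# biases driven by each neuron's own windowed average output.
#
# The slow subsystem is
#   tau_theta_i  d theta_i / dt = rho(<o_i>_{s_i}),
# co-integrated with the fast CTRNN at the same fixed step. Within one step
# the bias change is O(dt / tau_theta) <= 1e-4 * dt, so parameters are
# treated as frozen inside each fast RK4 step; biases are hard-clipped to
# the allowed range after every update.

#' Homeostatic activation function
#'
#' Piecewise-linear drive on a regulated bias as a function of the detected
#' mean activity `x`: positive (`LB - x`) below the target range, zero
#' inside `[LB, UB]`, negative (`UB - x`) above. Continuous everywhere.
#'
#' @param x detected mean activity in `[0, 1]` (vectorized).
#' @param LB,UB lower and upper bounds of the target activity range.
#' @return the regulation drive (same length as `x`).
#' @export
rho <- function(x, LB, UB = LB) {
  stopifnot(UB >= LB)
  ifelse(x < LB, LB - x, ifelse(x > UB, UB - x, 0))
}

#' ADHP mechanism
#'
#' Four meta-parameters per regulated bias: the lower bound of the target
#' activity range (`LB`), the range width (`delta`, with the upper bound
#' clipped at 1), the sliding-window length in seconds (`s`, 0 meaning
#' instantaneous detection), and the regulation time constant in seconds
#' (`tau_theta`). Regulation must be slow: `tau_theta` at least fifty
#' times every neural time constant (checked against the circuit at
#' simulation time).
#'
#' @param regulated character vector of regulated neurons (subset of
#'   LP/PY/PD).
#' @param LB named (or scalar) lower bounds in `[0, 1]`.
#' @param delta target range widths in `[0, 1]`; `UB = min(LB + delta, 1)`.
#' @param s sliding window lengths in seconds, in `[0, 10]`.
#' @param tau_theta regulation time constants in seconds (evolution
#'   restricts these to `[100, 200]`; larger values are allowed here for
#'   rate-invariance controls).
#' @param bias_range hard bounds on the regulated biases.
#' @return object of class `adhp_mechanism`.
#' @export
adhp_mechanism <- function(regulated = c("LP", "PD"), LB, delta = 0, s = 0,
                           tau_theta = 150, bias_range = c(-16, 16)) {
  regulated <- match.arg(regulated, NEURONS, several.ok = TRUE)
  expand <- function(x, what) {
    if (length(x) == 1L) x <- setNames(rep(x, length(regulated)), regulated)
    if (is.null(names(x))) names(x) <- regulated
    if (!setequal(names(x), regulated))
      stop(what, " must be named for the regulated neurons")
    x[regulated]
  }
  LB <- expand(LB, "LB")
  delta <- expand(delta, "delta")
  s <- expand(s, "s")
  tau_theta <- expand(tau_theta, "tau_theta")
  if (any(LB < 0 | LB > 1)) stop("LB must lie in [0, 1]")
  if (any(delta < 0 | delta > 1)) stop("delta must lie in [0, 1]")
  if (any(s < 0 | s > 10)) stop("window length s must lie in [0, 10] s")
  if (any(tau_theta <= 0)) stop("tau_theta must be positive")
  UB <- pmin(LB + delta, 1)
  structure(list(regulated = regulated, LB = LB, UB = UB, delta = delta,
                 s = s, tau_theta = tau_theta,
                 bias_range = as.numeric(bias_range)),
            class = "adhp_mechanism")
}

#' Zero-range ADHP mechanism targeting fixed activity values
#'
#' Convenience wrapper for the analytically tractable case `LB = UB = B`.
#'
#' @param B named target activity values per regulated neuron.
#' @inheritParams adhp_mechanism
#' @return an [adhp_mechanism()].
#' @export
zero_range_mechanism <- function(B, s = 0, tau_theta = 150,
                                 bias_range = c(-16, 16)) {
  adhp_mechanism(regulated = names(B), LB = B, delta = 0, s = s,
                 tau_theta = tau_theta, bias_range = bias_range)
}

#' @export
print.adhp_mechanism <- function(x, ...) {
  cat("<adhp_mechanism>  regulated:", paste(x$regulated, collapse = ", "),
      "\n")
  for (nm in x$regulated) {
    cat(sprintf("  %s: target [%.3f, %.3f]  s=%.2f s  tau_theta=%.1f s\n",
                nm, x$LB[[nm]], x$UB[[nm]], x$s[[nm]], x$tau_theta[[nm]]))
  }
  invisible(x)
}

check_timescales <- function(circuit, mechanism) {
  if (any(mechanism$tau_theta < 50 * max(circuit$tau)))
    stop("regulation too fast: tau_theta must be at least 50 times every ",
         "neural time constant (max tau = ", max(circuit$tau), " s)")
}

#' Simulate a circuit under homeostatic bias regulation
#'
#' Co-integrates the fast neural states and the slow regulated biases.
#' Regulated biases follow `d theta_i/dt = rho(<o_i>_s) / tau_theta_i` and
#' are hard-clipped to the bias range at every step. The sliding-window
#' average warms up over the first `s_i` seconds (averaging the available
#' samples); with `s_i = 0` the instantaneous output is used.
#'
#' @inheritParams integrate_ctrnn
#' @param mechanism an [adhp_mechanism()].
#' @param perturb optional named numeric: bias values to impose before the
#'   run (absolute values, as in the perturbation protocol).
#' @param duration regulation time in seconds.
#' @param record_every sampling interval (seconds) of the recorded bias and
#'   output trajectories.
#' @param equil equilibration time (seconds) with regulation off before
#'   ADHP engages.
#' @param early_exit allow the integrator to stop early when the full
#'   system is exactly frozen (fixed-point states and biases pinned or
#'   undriven) — the remaining trajectory is constant by construction.
#' @return object of class `adhp_trajectory` with `time`, `theta` (bias
#'   trajectories), `o` (output samples), final states, and the
#'   [classify_outcome()] record as `$outcome`.
#' @export
simulate_with_adhp <- function(circuit, mechanism, perturb = NULL,
                               duration = 5000, config = sim_config(),
                               record_every = 1, equil = 250,
                               initial = network_state(),
                               early_exit = FALSE) {
  stopifnot(inherits(circuit, "circuit_params"),
            inherits(mechanism, "adhp_mechanism"))
  check_dt(circuit, config)
  check_timescales(circuit, mechanism)
  pc <- if (is.null(perturb)) circuit else set_biases(circuit, perturb)
  if (!inherits(initial, "network_state")) initial <- network_state(initial)
  y0 <- initial$y
  if (equil > 0) {
    eq <- cpp_integrate(pc$tau, pc$theta, pc$w, y0, config$dt, equil, 0,
                        method_code(config))
    y0 <- eq$y[nrow(eq$y), ]
  }
  m <- mechanism
  res <- cpp_adhp_simulate(pc$tau, pc$theta, pc$w, y0,
                           match(m$regulated, NEURONS) - 1L, m$LB, m$UB,
                           m$s, m$tau_theta, config$dt, duration,
                           record_every, m$bias_range[1], m$bias_range[2],
                           method_code(config), early_exit)
  colnames(res$theta) <- NEURONS
  colnames(res$o) <- NEURONS
  traj <- structure(list(time = res$time, theta = res$theta, o = res$o,
                         y_final = res$y_final,
                         theta_final = res$theta_final,
                         terminated_early = res$terminated_early,
                         circuit = pc, mechanism = mechanism,
                         config = config),
                    class = "adhp_trajectory")
  traj$outcome <- classify_outcome(traj, circuit, config)
  traj
}

#' @export
print.adhp_trajectory <- function(x, ...) {
  cat(sprintf("<adhp_trajectory>  %.0f s of regulation on {%s}\n",
              max(x$time), paste(x$mechanism$regulated, collapse = ", ")))
  cat("  terminal biases:",
      paste(sprintf("%s=%.3f", NEURONS, x$theta_final), collapse = "  "),
      "\n")
  cat("  outcome:", x$outcome$classification, "\n")
  invisible(x)
}

#' Classify the terminal behaviour of a regulation run
#'
#' Inspects the trailing window of the recorded bias trajectory:
#' * `interior endpoint` — trailing bias excursion below `endpoint_tol`
#'   with biases off the hard bounds (in practice a small-amplitude
#'   parametric limit cycle around a nullcline intersection);
#' * `boundary endpoint` — settled with at least one regulated bias pinned
#'   within `1e-3` of a bound;
#' * `parametric limit cycle` — excursion above `cycle_tol` with a
#'   recurrent, consistent period in the bias trajectory;
#' * `non-convergent` — anything else.
#'
#' @param traj an `adhp_trajectory` (or a list with `time` and a `theta`
#'   matrix).
#' @param circuit optional [circuit_params()]; when given, the pyloric
#'   status at the terminal biases (and phase-resolved along a parametric
#'   cycle) is evaluated with frozen parameters.
#' @param config [sim_config()] for the frozen-parameter probes.
#' @param endpoint_tol,cycle_tol trailing bias-excursion tolerances
#'   separating endpoints from parametric cycles (bias units).
#' @param trailing length (seconds) of the trailing window inspected.
#' @return object of class `outcome_record`.
#' @export
classify_outcome <- function(traj, circuit = NULL, config = sim_config(),
                             endpoint_tol = 0.05, cycle_tol = 0.5,
                             trailing = 2000) {
  mech <- traj$mechanism
  reg <- if (!is.null(mech)) mech$regulated else NEURONS
  bias_range <- if (!is.null(mech)) mech$bias_range else c(-16, 16)
  keep <- traj$time >= max(traj$time) - trailing
  th <- traj$theta[keep, reg, drop = FALSE]
  tt <- traj$time[keep]
  exc <- apply(th, 2, function(v) diff(range(v)))
  terminal <- th[nrow(th), ]
  pinned <- abs(terminal - bias_range[1]) < 1e-3 |
    abs(terminal - bias_range[2]) < 1e-3
  cls <- NULL
  cycle_period <- NA_real_
  if (max(exc) < endpoint_tol) {
    cls <- if (any(pinned)) "boundary endpoint" else "interior endpoint"
  } else if (max(exc) > cycle_tol) {
    # recurrence detection on the dimension with the largest excursion
    d <- reg[which.max(exc)]
    v <- th[, d]
    mid <- (max(v) + min(v)) / 2
    up <- which(v[-length(v)] <= mid & v[-1] > mid)
    if (length(up) >= 3) {
      iv <- diff(tt[up])
      if (length(iv) >= 2 &&
          max(abs(iv - mean(iv))) < 0.15 * mean(iv)) {
        cls <- "parametric limit cycle"
        cycle_period <- mean(iv)
      }
    }
  }
  if (is.null(cls)) cls <- "non-convergent"
  bbox <- apply(th, 2, range)
  rownames(bbox) <- c("min", "max")
  pyloric_end <- NA
  pyloric_cycle <- NULL
  if (!is.null(circuit)) {
    frozen_status <- function(theta_vals) {
      fc <- set_biases(circuit, theta_vals)
      bd <- evaluate_circuit(fc, config)
      abs(bd$P_b - 0.3) < 1e-12
    }
    pyloric_end <- frozen_status(terminal)
    if (cls == "parametric limit cycle") {
      ph_idx <- unique(round(seq(max(1, nrow(th) -
        ceiling(cycle_period / diff(tt[1:2]))), nrow(th), length.out = 8)))
      pyloric_cycle <- vapply(ph_idx, function(k)
        frozen_status(th[k, ]), logical(1))
    }
  }
  structure(list(classification = cls, terminal_bias = terminal,
                 bounding_box = bbox, excursion = exc,
                 cycle_period = cycle_period, pyloric = pyloric_end,
                 pyloric_along_cycle = pyloric_cycle),
            class = "outcome_record")
}

#' @export
print.outcome_record <- function(x, ...) {
  cat("<outcome_record> ", x$classification, "\n")
  cat("  terminal biases:",
      paste(sprintf("%s=%.3f", names(x$terminal_bias), x$terminal_bias),
            collapse = "  "), "\n")
  if (!is.na(x$pyloric)) cat("  pyloric at end:", x$pyloric, "\n")
  if (is.finite(x$cycle_period))
    cat("  cycle period:", sprintf("%.0f s", x$cycle_period), "\n")
  invisible(x)
}
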