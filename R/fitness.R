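# Staged pyloricness fitness, timing bonus, and the ADHP recovery fitness.

#' Experimental timing statistics
#'
#' Means and standard deviations of the five relative timing metrics used
#' by the timing bonus: duty cycles of all three neurons and burst-start
#' phases (relative to PD) of LP and PY. Duty-cycle means of roughly
#' 0.264 (LP), 0.348 (PY) and 0.385 (PD) are reported for lobster
#' preparations; the standard deviations and phase statistics must be
#' supplied from the experimental literature — no defaults are invented.
#'
#' @param duty_mean,duty_sd named numeric (LP, PY, PD).
#' @param phase_mean,phase_sd named numeric (LP, PY).
#' @return object of class `timing_stats`.
#' @export
timing_stats <- function(duty_mean, duty_sd, phase_mean, phase_sd) {
  duty_mean <- named3(duty_mean, "duty_mean")
  duty_sd <- named3(duty_sd, "duty_sd")
  named2 <- function(x, what) {
    if (is.null(names(x))) names(x) <- c("LP", "PY")
    if (!setequal(names(x), c("LP", "PY")))
      stop(what, " must be named with LP, PY")
    x[c("LP", "PY")]
  }
  phase_mean <- named2(phase_mean, "phase_mean")
  phase_sd <- named2(phase_sd, "phase_sd")
  if (any(c(duty_sd, phase_sd) <= 0)) stop("all SDs must be positive")
  if (any(c(duty_mean, phase_mean) <= 0 | c(duty_mean, phase_mean) >= 1))
    stop("all means must lie in (0, 1)")
  structure(list(duty_mean = duty_mean, duty_sd = duty_sd,
                 phase_mean = phase_mean, phase_sd = phase_sd),
            class = "timing_stats")
}

#' Base pyloricness fitness
#'
#' Awarded in all-or-nothing 0.05 steps: one step per neuron whose output
#' crosses the burst threshold in both directions, plus (only when all
#' three burst) one step per satisfied ordering criterion:
#' \eqn{P_b = 0.05\,(n + [n = 3](c_{gap} + c_{PY_S<LP_E} + c_{LP_E<PY_E}))}.
#' A circuit is pyloric exactly when \eqn{P_b = 0.3}.
#'
#' @param n number of bursting neurons (0-3).
#' @param criteria logical vector of the three ordering criteria.
#' @return the base fitness, a multiple of 0.05 in `[0, 0.3]`.
#' @export
base_fitness <- function(n, criteria = c(FALSE, FALSE, FALSE)) {
  stopifnot(n %in% 0:3, length(criteria) == 3L)
  0.05 * (n + (n == 3L) * sum(criteria))
}

#' Timing bonus fitness
#'
#' Bonus awarded for similarity to experimentally observed burst timing:
#' \eqn{P_t = 5 / (\sum_i |z(d_i)| + \sum_j |z(\phi_j)|)} over the three
#' duty cycles and the LP and PY start phases, with
#' \eqn{z = (x - \bar x)/s_x}. Only defined for pyloric rhythms
#' (\eqn{P_b = 0.3}). The denominator is floored at `eps` so that a rhythm
#' exactly at all experimental means scores a large, finite bonus (flagged
#' via attribute `"at_mean"`).
#'
#' @param metrics list with `duty` (LP/PY/PD) and `phase` (LP/PY at least),
#'   as produced by [timing_metrics()] or [analyze_rhythm()].
#' @param stats a [timing_stats()] object.
#' @param eps denominator floor.
#' @return the timing bonus (numeric scalar).
#' @export
timing_fitness <- function(metrics, stats, eps = 1e-6) {
  stopifnot(inherits(stats, "timing_stats"))
  d <- metrics$duty[NEURONS]
  ph <- metrics$phase[c("LP", "PY")]
  if (any(!is.finite(c(d, ph))))
    stop("timing metrics undefined: timing fitness requires a pyloric",
         " rhythm with one burst per neuron per cycle")
  z <- sum(abs((d - stats$duty_mean) / stats$duty_sd)) +
    sum(abs((ph - stats$phase_mean) / stats$phase_sd))
  structure(5 / max(z, eps), at_mean = z < eps)
}

#' Total fitness
#'
#' \eqn{P = P_b + [P_b = 0.3]\,P_t}: the timing bonus counts only for
#' pyloric rhythms.
#'
#' @param P_b base fitness.
#' @param P_t timing bonus (`NA` or `NULL` when not evaluated).
#' @return total fitness.
#' @export
total_fitness <- function(P_b, P_t = NA_real_) {
  bonus <- if (abs(P_b - 0.3) < 1e-12 && length(P_t) && is.finite(P_t))
    as.numeric(P_t) else 0
  P_b + bonus
}

#' Evaluate a circuit's pyloric fitness
#'
#' Simulates the circuit (transient then recording window), analyzes the
#' rhythm, and assembles the full fitness breakdown.
#'
#' @inheritParams integrate_ctrnn
#' @param stats optional [timing_stats()]; when supplied and the rhythm is
#'   pyloric, the timing bonus is included in the total.
#' @return object of class `fitness_breakdown`: `n`, `criteria`, `P_b`,
#'   `P_t` (NA when undefined), `P`, and the `rhythm` descriptor.
#' @export
evaluate_circuit <- function(circuit, config = sim_config(), stats = NULL,
                             initial = network_state()) {
  desc <- tryCatch({
    traj <- integrate_ctrnn(circuit, initial, config)
    analyze_rhythm(traj, config)
  }, error = function(e) NULL)
  if (is.null(desc)) {
    return(structure(list(n = 0L, criteria = setNames(rep(FALSE, 3),
             c("gap", "PYS_before_LPE", "LPE_before_PYE")),
             P_b = 0, P_t = NA_real_, P = 0, rhythm = NULL,
             failed = TRUE), class = "fitness_breakdown"))
  }
  P_b <- base_fitness(desc$n_bursting, desc$criteria)
  P_t <- NA_real_
  if (!is.null(stats) && desc$pyloric)
    P_t <- as.numeric(timing_fitness(desc, stats))
  structure(list(n = desc$n_bursting, criteria = desc$criteria, P_b = P_b,
                 P_t = P_t, P = total_fitness(P_b, P_t), rhythm = desc,
                 failed = FALSE),
            class = "fitness_breakdown")
}

#' @export
print.fitness_breakdown <- function(x, ...) {
  cat(sprintf("<fitness_breakdown>  n=%d  P_b=%.2f  P_t=%s  P=%.4g\n",
              x$n, x$P_b,
              if (is.finite(x$P_t)) sprintf("%.4g", x$P_t) else "undef",
              x$P))
  invisible(x)
}

#' ADHP evaluation protocol
#'
#' Settings for scoring a homeostatic mechanism on a circuit: the absolute
#' bias values (LP and PD, or all regulated neurons) to which the circuit
#' is perturbed, the pre-regulation equilibration time, the measurement
#' checkpoints, and the flat per-measurement pyloricness bonus.
#'
#' @param perturb_values bias values of the perturbation grid per regulated
#'   dimension (default `c(-9, 0, 9)`, giving a 3x3 grid for 2D ADHP).
#' @param equil equilibration before regulation starts, seconds.
#' @param checkpoints regulation times (seconds) at which pyloric fitness
#'   is measured with parameters momentarily frozen.
#' @param alpha flat bonus added whenever a measurement is pyloric.
#' @param config [sim_config()] used for simulation and measurement.
#' @param stats optional [timing_stats()] used for the timing part of P.
#' @return list of class `adhp_protocol`.
#' @export
adhp_protocol <- function(perturb_values = c(-9, 0, 9), equil = 250,
                          checkpoints = c(2500, 5000), alpha = 25,
                          config = sim_config(), stats = NULL) {
  structure(list(perturb_values = perturb_values, equil = equil,
                 checkpoints = sort(checkpoints), alpha = alpha,
                 config = config, stats = stats),
            class = "adhp_protocol")
}

#' ADHP fitness of a mechanism on a circuit
#'
#' For every point of the perturbation grid, the regulated biases are set
#' to the grid value, the network equilibrates with regulation off, then
#' ADHP runs continuously; pyloric fitness (with the flat pyloricness
#' bonus \eqn{\alpha}) is measured at each checkpoint with parameters
#' frozen. The ADHP fitness `A` is the mean of all measurements:
#' \eqn{A = \frac{1}{18}\sum_{i=1}^{9}
#'   ([P + [P_b{=}0.3]\alpha]_{t_1} + [P + [P_b{=}0.3]\alpha]_{t_2})}
#' for the default 3x3 grid and two checkpoints. A leg whose integration
#' fails scores 0 and is logged.
#'
#' @param circuit a [circuit_params()] object.
#' @param mechanism an [adhp_mechanism()].
#' @param protocol an [adhp_protocol()].
#' @return list with `A`, the per-measurement table `measurements`, and
#'   `failures` (character log of failed legs).
#' @export
adhp_fitness <- function(circuit, mechanism, protocol = adhp_protocol()) {
  stopifnot(inherits(mechanism, "adhp_mechanism"))
  reg <- mechanism$regulated
  grid <- do.call(expand.grid,
                  setNames(rep(list(protocol$perturb_values), length(reg)),
                           reg))
  rows <- list()
  failures <- character(0)
  for (g in seq_len(nrow(grid))) {
    pert <- setNames(as.numeric(grid[g, ]), reg)
    scores <- tryCatch(
      adhp_checkpoint_scores(circuit, mechanism, pert, protocol),
      error = function(e) {
        failures <<- c(failures,
                       sprintf("perturbation %s: %s",
                               paste(pert, collapse = ","),
                               conditionMessage(e)))
        data.frame(t = protocol$checkpoints, P = 0, P_b = 0,
                   pyloric = FALSE)
      })
    scores$grid_index <- g
    for (nm in reg) scores[[paste0("perturb_", nm)]] <- pert[[nm]]
    rows[[g]] <- scores
  }
  meas <- do.call(rbind, rows)
  A <- mean(meas$P + protocol$alpha * meas$pyloric)
  list(A = A, measurements = meas, failures = failures)
}

# run regulation between checkpoints, measuring frozen-parameter fitness
adhp_checkpoint_scores <- function(circuit, mechanism, pert, protocol) {
  cfg <- protocol$config
  pc <- set_biases(circuit, pert)
  res <- cpp_integrate(pc$tau, pc$theta, pc$w, c(0, 0, 0), cfg$dt,
                       protocol$equil, 0, method_code(cfg))
  y <- res$y[nrow(res$y), ]
  theta <- pc$theta
  t_prev <- 0
  out <- data.frame()
  for (tc in protocol$checkpoints) {
    seg <- run_adhp_segment(circuit, mechanism, theta, y, tc - t_prev, cfg)
    y <- seg$y_final
    theta <- seg$theta_final
    t_prev <- tc
    frozen <- set_biases(circuit, setNames(theta[NEURONS], NEURONS))
    bd <- evaluate_circuit(frozen, cfg, protocol$stats,
                           network_state(setNames(y[NEURONS], NEURONS)))
    out <- rbind(out, data.frame(t = tc, P = bd$P, P_b = bd$P_b,
                                 pyloric = abs(bd$P_b - 0.3) < 1e-12))
  }
  out
}

run_adhp_segment <- function(circuit, mechanism, theta, y, duration, cfg) {
  m <- mechanism
  res <- cpp_adhp_simulate(circuit$tau, theta, circuit$w, y,
                           match(m$regulated, NEURONS) - 1L,
                           m$LB, m$UB, m$s, m$tau_theta, cfg$dt, duration,
                           duration, m$bias_range[1], m$bias_range[2],
                           method_code(cfg), FALSE)
  list(y_final = res$y_final, theta_final = res$theta_final)
}

#' Post-hoc robustness grid test
#'
#' Re-tests a mechanism on a denser/wider perturbation grid (default the
#' 6x6 grid `{-15,-9,-3,3,9,15}^2`) and labels it by the fraction of
#' perturbations from which pyloricness is recovered at the final
#' checkpoint: `"full"` (all), `"mixed"` (some), `"none"`.
#'
#' @inheritParams adhp_fitness
#' @param values perturbation bias values per regulated dimension.
#' @return list with `label`, `recovered`, `n`, and the measurement table.
#' @export
robustness_test <- function(circuit, mechanism,
                            values = c(-15, -9, -3, 3, 9, 15),
                            protocol = adhp_protocol()) {
  protocol$perturb_values <- values
  fit <- adhp_fitness(circuit, mechanism, protocol)
  final <- fit$measurements[fit$measurements$t == max(protocol$checkpoints), ]
  rec <- sum(final$pyloric)
  n <- nrow(final)
  label <- if (rec == n) "full" else if (rec > 0) "mixed" else "none"
  list(label = label, recovered = rec, n = n,
       measurements = fit$measurements)
}
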