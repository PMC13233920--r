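# CTRNN core: parameter container, sigmoid, fixed-step integration and
# limit-set equilibration for the three-neuron pyloric model.

#' Logistic activation function
#'
#' \eqn{\sigma(x) = 1/(1 + e^{-x})}, the output nonlinearity of every model
#' neuron. Saturates smoothly without overflow for large `|x|`.
#'
#' @param x numeric vector.
#' @return values in (0, 1).
#' @export
#' @examples
#' sigma(0)       # 0.5
#' sigma(3) + sigma(-3)  # 1
sigma <- function(x) {
  out <- numeric(length(x))
  pos <- !is.na(x) & x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  e <- exp(x[!pos])
  out[!pos] <- e / (1 + e)
  out[is.na(x)] <- NA_real_
  out
}

#' Inverse of the logistic activation
#' @param p values in (0, 1).
#' @return numeric vector.
#' @export
logit <- function(p) log(p / (1 - p))

named3 <- function(x, what) {
  if (length(x) == 1L) x <- rep(x, 3L)
  if (is.null(names(x))) names(x) <- NEURONS
  if (!setequal(names(x), NEURONS))
    stop(what, " must be named with LP, PY, PD")
  x[NEURONS]
}

#' Circuit parameter set
#'
#' The 15 free parameters of the three-neuron CTRNN: a time constant
#' \eqn{\tau_i} (seconds) and output bias \eqn{\theta_i} per neuron, and the
#' nine synaptic weights \eqn{w_{i \to j}}. Neurons are labelled LP, PY and
#' PD after the pyloric cell types they stand for.
#'
#' @param tau named numeric, time constants in seconds; allowed range
#'   `[0.1, 2]`.
#' @param theta named numeric, biases; allowed range `[-16, 16]`.
#' @param w 3x3 numeric matrix, `w[i, j]` is the weight from neuron `i` to
#'   neuron `j` (rows/columns ordered LP, PY, PD), or a named vector with
#'   names like `w_LP_to_PY`.
#' @param weight_range numeric length 2, allowed weight range (the weight
#'   bounds are a modelling choice; the default matches the bias range).
#' @return an object of class `circuit_params`.
#' @export
circuit_params <- function(tau, theta, w, weight_range = c(-16, 16)) {
  tau <- named3(tau, "tau")
  theta <- named3(theta, "theta")
  if (is.matrix(w)) {
    stopifnot(all(dim(w) == c(3L, 3L)))
    dimnames(w) <- list(NEURONS, NEURONS)
  } else {
    wm <- matrix(NA_real_, 3, 3, dimnames = list(NEURONS, NEURONS))
    for (i in NEURONS) for (j in NEURONS) {
      key <- paste0("w_", i, "_to_", j)
      if (!key %in% names(w)) stop("missing weight ", key)
      wm[i, j] <- w[[key]]
    }
    w <- wm
  }
  if (any(!is.finite(tau)) || any(tau < 0.1 - 1e-12) || any(tau > 2 + 1e-12))
    stop("time constants must lie in [0.1, 2] seconds")
  if (any(!is.finite(theta)) || any(abs(theta) > 16 + 1e-12))
    stop("biases must lie in [-16, 16]")
  if (any(!is.finite(w)))
    stop("all 9 weights must be present and finite")
  if (any(w < min(weight_range) - 1e-9) || any(w > max(weight_range) + 1e-9))
    stop("weights outside the configured range [", weight_range[1], ", ",
         weight_range[2], "]")
  structure(list(tau = tau, theta = theta, w = w,
                 weight_range = as.numeric(weight_range)),
            class = "circuit_params")
}

#' @export
print.circuit_params <- function(x, ...) {
  cat("<circuit_params>  three-neuron CTRNN\n")
  cat("  tau   :", paste(sprintf("%s=%.4g", NEURONS, x$tau), collapse = "  "),
      "\n")
  cat("  theta :", paste(sprintf("%s=%.4g", NEURONS, x$theta),
                         collapse = "  "), "\n")
  cat("  weights (source -> target):\n")
  print(round(x$w, 4))
  invisible(x)
}

#' Replace biases of a circuit
#'
#' Convenience used for perturbations and grid scans: returns a copy of the
#' circuit with some biases set to new values.
#'
#' @param circuit a [circuit_params()] object.
#' @param theta named numeric of biases to replace (subset of LP/PY/PD).
#' @return a `circuit_params` object.
#' @export
set_biases <- function(circuit, theta) {
  stopifnot(inherits(circuit, "circuit_params"))
  th <- circuit$theta
  th[names(theta)] <- theta
  circuit$theta <- th
  circuit
}

#' Network state
#'
#' @param y named numeric, one state per neuron.
#' @param time non-negative time in seconds.
#' @return object of class `network_state`.
#' @export
network_state <- function(y = c(LP = 0, PY = 0, PD = 0), time = 0) {
  y <- named3(y, "y")
  if (any(!is.finite(y)) || !is.finite(time) || time < 0)
    stop("states must be finite and time non-negative")
  structure(list(y = y, time = time), class = "network_state")
}

#' Simulation configuration
#'
#' @param dt integration step in seconds (fixed step).
#' @param transient seconds of simulation discarded before recording.
#' @param record seconds of trajectory recorded.
#' @param threshold burst threshold on neuron outputs, in (0, 1).
#' @param method `"rk4"` (default) or `"euler"` (provided for
#'   order-of-accuracy cross-checks).
#' @param nonosc_window averaging window (seconds) used for cycle averages
#'   of non-oscillatory circuits.
#' @param period_tol relative tolerance for consistency of successive
#'   inter-burst intervals during period detection.
#' @param min_gap minimum silent-gap duration (seconds) required before the
#'   LP burst onset for the gap criterion; 0 means the instantaneous test.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(dt = 0.01, transient = 50, record = 50,
                       threshold = 0.5, method = c("rk4", "euler"),
                       nonosc_window = 50, period_tol = 0.01, min_gap = 0) {
  method <- match.arg(method)
  if (dt <= 0) stop("dt must be positive")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  structure(list(dt = dt, transient = transient, record = record,
                 threshold = threshold, method = method,
                 nonosc_window = nonosc_window, period_tol = period_tol,
                 min_gap = min_gap),
            class = "sim_config")
}

method_code <- function(config) if (config$method == "euler") 1L else 0L

check_dt <- function(circuit, config) {
  if (config$dt > min(circuit$tau) / 10 + 1e-12)
    stop("dt = ", config$dt, " too large for the stiffest time constant ",
         min(circuit$tau), " (need dt <= min tau / 10)")
}

#' Integrate the CTRNN with frozen parameters
#'
#' Numerically integrates the three coupled leaky-integrator equations
#' \eqn{\tau_i \, dy_i/dt = -y_i + \sum_j w_{j \to i} \sigma(y_j + \theta_j)}
#' with a fixed-step scheme, discards the transient, and records states and
#' outputs on a uniform time grid.
#'
#' @param circuit a [circuit_params()] object.
#' @param initial a [network_state()] or a plain numeric vector of initial
#'   states (default: the origin).
#' @param config a [sim_config()].
#' @return object of class `ctrnn_trajectory` with elements `time`, `y`
#'   (states, one column per neuron) and `o` (outputs in (0, 1)).
#' @export
integrate_ctrnn <- function(circuit, initial = network_state(),
                            config = sim_config()) {
  stopifnot(inherits(circuit, "circuit_params"))
  if (!inherits(initial, "network_state")) initial <- network_state(initial)
  check_dt(circuit, config)
  res <- cpp_integrate(circuit$tau, circuit$theta, circuit$w, initial$y,
                       config$dt, config$transient, config$record,
                       method_code(config))
  colnames(res$y) <- NEURONS
  colnames(res$o) <- NEURONS
  structure(list(time = res$time, y = res$y, o = res$o, dt = config$dt,
                 circuit = circuit, config = config),
            class = "ctrnn_trajectory")
}

#' @export
print.ctrnn_trajectory <- function(x, ...) {
  cat(sprintf("<ctrnn_trajectory>  %d samples, t in [%.4g, %.4g] s, dt = %g\n",
              length(x$time), min(x$time), max(x$time), x$dt))
  invisible(x)
}

#' Run the transient and classify the limit set
#'
#' Simulates the circuit for the configured transient, then inspects a test
#' window: if states barely move the behaviour is a fixed point; if outputs
#' show recurrent threshold crossings with a consistent period it is
#' oscillatory; anything else is reported as `"unclassified"` (treated as
#' non-pyloric downstream).
#'
#' @inheritParams integrate_ctrnn
#' @param tol maximum per-neuron state excursion over the test window for a
#'   fixed-point classification.
#' @return list with `state` (the settled [network_state()]),
#'   `classification` (`"fixed"`, `"oscillatory"` or `"unclassified"`), and
#'   the recorded test `trajectory`.
#' @export
equilibrate <- function(circuit, initial = network_state(),
                        config = sim_config(), tol = 1e-6) {
  traj <- integrate_ctrnn(circuit, initial, config)
  n <- nrow(traj$y)
  excursion <- max(apply(traj$y, 2, function(v) diff(range(v))))
  an <- analyze_rhythm(traj)
  cls <- if (an$oscillatory) "oscillatory"
         else if (excursion < tol) "fixed"
         else "unclassified"
  state <- network_state(traj$y[n, ], time = traj$time[n])
  list(state = state, classification = cls, trajectory = traj)
}
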