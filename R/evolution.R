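# Microbial (steady-state) genetic algorithm for evolving pyloric circuits
# and homeostatic mechanisms. Genomes are vectors of unit-interval genes
# mapped affinely onto parameter ranges; selection is tournament-of-two
# with the mutated winner copied over the loser, so the best individual is
# never lost.

#' GA configuration
#'
#' @param pop_size population size.
#' @param generations number of generations; one generation is `pop_size`
#'   tournaments.
#' @param mutation_sd per-gene Gaussian mutation SD in genome space,
#'   reflected at the `[0, 1]` bounds.
#' @param seed integer seed; every run is fully reproducible from it.
#' @return list of class `ga_config`.
#' @export
ga_config <- function(pop_size = 100, generations = 100,
                      mutation_sd = 0.05, seed = 1) {
  stopifnot(pop_size >= 2, generations >= 1, mutation_sd > 0)
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 mutation_sd = mutation_sd, seed = as.integer(seed)),
            class = "ga_config")
}

reflect01 <- function(x) {
  # reflect into [0, 1] (mutations are small, so one fold suffices in
  # practice; loop for safety)
  while (any(x < 0 | x > 1)) {
    x[x < 0] <- -x[x < 0]
    x[x > 1] <- 2 - x[x > 1]
  }
  x
}

#' Run the microbial GA
#'
#' Steady-state tournament scheme: two distinct individuals are drawn at
#' random, and a mutated copy of the fitter one replaces the other. Fitness
#' values are cached per individual, so each generation costs `pop_size`
#' evaluations.
#'
#' @param n_genes genome length.
#' @param fitness_fn function mapping a genome (numeric in `[0,1]`) to a
#'   scalar fitness (larger is better).
#' @param config a [ga_config()].
#' @return list with `best` genome, `best_fitness`, `history` (best fitness
#'   per generation), `population`, `fitness` and the `config`.
#' @export
run_microbial_ga <- function(n_genes, fitness_fn, config = ga_config()) {
  set.seed(config$seed)
  pop <- matrix(runif(config$pop_size * n_genes), config$pop_size, n_genes)
  fit <- apply(pop, 1, fitness_fn)
  history <- numeric(config$generations)
  for (gen in seq_len(config$generations)) {
    for (k in seq_len(config$pop_size)) {
      pair <- sample.int(config$pop_size, 2)
      w <- if (fit[pair[1]] >= fit[pair[2]]) pair[1] else pair[2]
      l <- setdiff(pair, w)[1]
      child <- reflect01(pop[w, ] +
                           rnorm(n_genes, sd = config$mutation_sd))
      pop[l, ] <- child
      fit[l] <- fitness_fn(child)
    }
    history[gen] <- max(fit)
  }
  b <- which.max(fit)
  list(best = pop[b, ], best_fitness = fit[b], history = history,
       population = pop, fitness = fit, config = config)
}

#' Decode a 15-gene genome into circuit parameters
#'
#' Gene order: the three time constants (LP, PY, PD), the three biases,
#' then the nine weights in source-major order (LP->LP, LP->PY, LP->PD,
#' PY->LP, ...). Ranges: tau in `[0.1, 2]` s, theta in `[-16, 16]`,
#' weights in `weight_range`.
#'
#' @param genes numeric vector of 15 genes in `[0, 1]`.
#' @param weight_range allowed weight range (a modelling choice; the
#'   default is symmetric with the bias range).
#' @return a [circuit_params()] object.
#' @export
decode_circuit <- function(genes, weight_range = c(-16, 16)) {
  stopifnot(length(genes) == 15L, all(genes >= 0 & genes <= 1))
  tau <- 0.1 + genes[1:3] * 1.9
  theta <- -16 + genes[4:6] * 32
  w <- matrix(weight_range[1] + genes[7:15] * diff(weight_range),
              3, 3, byrow = TRUE)
  circuit_params(setNames(tau, NEURONS), setNames(theta, NEURONS), w,
                 weight_range)
}

#' Encode circuit parameters back into genome space
#' @inheritParams decode_circuit
#' @param circuit a [circuit_params()] object.
#' @return numeric vector of 15 genes (round-trips with [decode_circuit()]).
#' @export
encode_circuit <- function(circuit, weight_range = circuit$weight_range) {
  unname(c((circuit$tau - 0.1) / 1.9, (circuit$theta + 16) / 32,
           (as.vector(t(circuit$w)) - weight_range[1]) /
             diff(weight_range)))
}

#' Decode an ADHP genome (4 genes per regulated neuron)
#'
#' Per regulated neuron, in order: `LB` in `[0, 1]`, range width `delta`
#' in `[0, 1]` (upper bound clipped at 1), window `s` in `[0, 10]` s, and
#' `tau_theta` in `[100, 200]` s.
#'
#' @param genes numeric vector of `4 * length(regulated)` genes.
#' @param regulated regulated neuron labels.
#' @return an [adhp_mechanism()].
#' @export
decode_mechanism <- function(genes, regulated = c("LP", "PD")) {
  stopifnot(length(genes) == 4L * length(regulated))
  g <- matrix(genes, ncol = 4, byrow = TRUE)
  adhp_mechanism(regulated = regulated,
                 LB = setNames(g[, 1], regulated),
                 delta = setNames(g[, 2], regulated),
                 s = setNames(g[, 3] * 10, regulated),
                 tau_theta = setNames(100 + g[, 4] * 100, regulated))
}

#' Encode an ADHP mechanism into genome space
#' @param mechanism an [adhp_mechanism()].
#' @return numeric genome (round-trips with [decode_mechanism()]).
#' @export
encode_mechanism <- function(mechanism) {
  as.vector(t(cbind(mechanism$LB, mechanism$delta, mechanism$s / 10,
                    (mechanism$tau_theta - 100) / 100)))
}

#' Evolve a pyloric circuit
#'
#' Runs the microbial GA against the pyloricness fitness. In `"base"` mode
#' the objective is the staged base fitness `P_b`; in `"timing"` mode the
#' total fitness `P` including the timing bonus (which requires `stats`).
#' The returned run records whether the best circuit is admissible to the
#' order-only database (`P_b = 0.3`) and the well-timed database
#' (`P >= 2`).
#'
#' @param config a [ga_config()].
#' @param mode `"base"` or `"timing"`.
#' @param stats a [timing_stats()] (required for `"timing"`).
#' @param sim a [sim_config()] used for every evaluation.
#' @param weight_range allowed weight range.
#' @return list with `circuit`, `breakdown`, `admit_base`, `admit_timing`,
#'   `history`, and the configs (the run log).
#' @export
evolve_circuits <- function(config = ga_config(),
                            mode = c("base", "timing"), stats = NULL,
                            sim = sim_config(), weight_range = c(-16, 16)) {
  mode <- match.arg(mode)
  if (mode == "timing" && is.null(stats))
    stop("timing mode requires timing_stats")
  fit_fn <- function(genes) {
    bd <- evaluate_circuit(decode_circuit(genes, weight_range), sim,
                           if (mode == "timing") stats else NULL)
    if (mode == "timing") bd$P else bd$P_b
  }
  run <- run_microbial_ga(15L, fit_fn, config)
  circuit <- decode_circuit(run$best, weight_range)
  bd <- evaluate_circuit(circuit, sim, stats)
  list(circuit = circuit, breakdown = bd,
       admit_base = abs(bd$P_b - 0.3) < 1e-12,
       admit_timing = abs(bd$P_b - 0.3) < 1e-12 && isTRUE(bd$P >= 2),
       history = run$history, ga = config, sim = sim,
       weight_range = weight_range, mode = mode)
}

#' Evolve an ADHP mechanism for a circuit
#'
#' Same GA engine, with the ADHP recovery fitness `A` as objective. The
#' best mechanism is then labelled by the post-hoc robustness grid test.
#'
#' @param circuit the circuit to regulate.
#' @param config a [ga_config()].
#' @param protocol an [adhp_protocol()].
#' @param regulated which biases the mechanism regulates.
#' @param robustness_values perturbation values for the post-hoc test
#'   (default the 6x6 grid).
#' @return list with `mechanism`, `A`, `label`, `robustness`, `history`
#'   and the configs.
#' @export
evolve_adhp <- function(circuit, config = ga_config(pop_size = 50),
                        protocol = adhp_protocol(),
                        regulated = c("LP", "PD"),
                        robustness_values = c(-15, -9, -3, 3, 9, 15)) {
  fit_fn <- function(genes) {
    adhp_fitness(circuit, decode_mechanism(genes, regulated), protocol)$A
  }
  run <- run_microbial_ga(4L * length(regulated), fit_fn, config)
  mech <- decode_mechanism(run$best, regulated)
  rob <- robustness_test(circuit, mech, robustness_values, protocol)
  list(mechanism = mech, A = run$best_fitness, label = rob$label,
       robustness = rob, history = run$history, ga = config,
       protocol = protocol)
}

#' Meta-parameter census across evaluated mechanisms
#'
#' Collects the four meta-parameters of each mechanism per regulated
#' neuron, split by success label, for distributional comparison (for
#' example, target-range widths of fully successful regulators tend to be
#' stochastically smaller than those of failing ones).
#'
#' @param runs list of results from [evolve_adhp()] (or any list with
#'   `mechanism` and `label`).
#' @return data frame with one row per (mechanism, regulated neuron).
#' @export
metaparameter_census <- function(runs) {
  stopifnot(length(runs) >= 1)
  rows <- lapply(seq_along(runs), function(k) {
    m <- runs[[k]]$mechanism
    data.frame(mechanism = k, neuron = m$regulated,
               LB = unname(m$LB), delta = unname(m$delta),
               s = unname(m$s), tau_theta = unname(m$tau_theta),
               label = runs[[k]]$label, row.names = NULL)
  })
  do.call(rbind, rows)
}
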