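# Rhythm analysis: parse output traces into bursts, detect the period,
# fold one cycle anchored at the LP burst onset, classify the burst-event
# ordering, and evaluate the three pyloric criteria.
#
# Conventions (all deliberate and used consistently):
#   * threshold comparisons are strict: a sample exactly at threshold
#     counts as below (not bursting);
#   * burst boundaries are located by linear interpolation between the two
#     samples straddling the threshold;
#   * a cycle starts at the LP burst onset (LP_S); bursts of PY and PD may
#     wrap the cycle boundary;
#   * events closer together than one sample step are ties, which make the
#     ordering undefined and the rhythm non-pyloric.

crossing_times <- function(time, o, threshold) {
  below <- o <= threshold
  k <- which(below[-length(o)] & !below[-1])
  ups <- time[k] + (time[k + 1] - time[k]) *
    (threshold - o[k]) / (o[k + 1] - o[k])
  k <- which(!below[-length(o)] & below[-1])
  downs <- time[k] + (time[k + 1] - time[k]) *
    (threshold - o[k]) / (o[k + 1] - o[k])
  list(ups = ups, downs = downs)
}

#' Parse a trajectory into burst trains
#'
#' Splits each neuron's output series into burst episodes (maximal epochs
#' with output strictly above the threshold). Episode boundaries are found
#' by linear interpolation between samples; only complete episodes (an
#' upward crossing followed by a downward one) are listed.
#'
#' @param trajectory a `ctrnn_trajectory` (or any list with `time` and an
#'   `o` matrix with columns LP, PY, PD).
#' @param threshold burst threshold (default 0.5).
#' @return named list of `burst_train` objects, each with `neuron`,
#'   `status` (`"bursting"`, `"silent"` or `"tonic"`), an `episodes` matrix
#'   with columns `start`/`end`, and the raw crossing times `ups`, `downs`.
#' @export
parse_bursts <- function(trajectory, threshold = 0.5) {
  stopifnot(length(trajectory$time) > 0)
  dt <- trajectory$time[2] - trajectory$time[1]
  out <- lapply(NEURONS, function(nm) {
    o <- trajectory$o[, nm]
    cr <- crossing_times(trajectory$time, o, threshold)
    above <- any(o > threshold)
    below <- any(o <= threshold)
    status <- if (above && below) "bursting" else if (above) "tonic"
              else "silent"
    # pair each upward crossing with the next downward crossing
    eps <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("start", "end")))
    for (u in cr$ups) {
      d <- cr$downs[cr$downs > u]
      if (length(d)) eps <- rbind(eps, c(u, d[1]))
    }
    structure(list(neuron = nm, status = status, episodes = eps,
                   ups = cr$ups, downs = cr$downs, dt = dt,
                   t_range = range(trajectory$time)),
              class = "burst_train")
  })
  names(out) <- NEURONS
  out
}

#' Detect the rhythm period
#'
#' Estimates the period from successive upward threshold crossings of a
#' reference neuron (LP, falling back to PY then PD), requiring at least
#' three consecutive inter-crossing intervals that agree within a relative
#' tolerance. Fixed points and inconsistent interval sequences yield `NA`.
#'
#' @inheritParams parse_bursts
#' @param rel_tol relative agreement tolerance between successive
#'   inter-crossing intervals (default 1\%).
#' @return the period in seconds, or `NA_real_` when undefined.
#' @export
detect_period <- function(trajectory, threshold = 0.5, rel_tol = 0.01) {
  bursts <- if (inherits(trajectory, "burst_train_set")) trajectory
            else parse_bursts(trajectory, threshold)
  for (nm in NEURONS) {
    T <- period_from_crossings(bursts[[nm]]$ups, rel_tol)
    if (is.finite(T)) return(T)
  }
  NA_real_
}

period_from_crossings <- function(ups, rel_tol = 0.01) {
  m <- length(ups)
  if (m < 4) return(NA_real_)
  d <- diff(ups)
  used <- 0L
  s <- 0
  ref <- d[length(d)]
  for (k in rev(seq_along(d))) {
    mean_so_far <- if (used > 0) s / used else ref
    if (abs(d[k] - mean_so_far) > rel_tol * mean_so_far) break
    s <- s + d[k]
    used <- used + 1L
    if (used >= 5L) break
  }
  if (used < 3L) return(NA_real_)
  s / used
}

# Latest pair of consecutive burst onsets of a neuron that is consistent
# with the detected period (the cycle is folded between actual onsets, so
# period jitter cannot spill the next onset into the window).
last_cycle_pair <- function(ups, period, tol = 0.05) {
  if (length(ups) < 2) return(NULL)
  for (k in rev(seq_len(length(ups) - 1))) {
    Tc <- ups[k + 1] - ups[k]
    if (abs(Tc - period) <= tol * period) return(c(ups[k], ups[k + 1]))
  }
  NULL
}

# Fold one LP_S-anchored cycle: returns up/down phases per neuron or NULL
# when folding is impossible (no full LP-anchored cycle, or a neuron does
# not have exactly one burst per cycle).
fold_cycle <- function(bursts, period) {
  if (!is.finite(period)) return(NULL)
  cyc <- last_cycle_pair(bursts$LP$ups, period)
  if (is.null(cyc)) return(NULL)
  anchor <- cyc[1]
  Tc <- cyc[2] - cyc[1]
  up_ph <- down_ph <- setNames(numeric(3), NEURONS)
  for (nm in NEURONS) {
    u <- bursts[[nm]]$ups
    d <- bursts[[nm]]$downs
    u <- u[u >= anchor - 1e-12 & u < cyc[2] - 1e-12]
    d <- d[d >= anchor - 1e-12 & d < cyc[2] - 1e-12]
    if (length(u) != 1L || length(d) != 1L) return(NULL)
    up_ph[nm] <- (u - anchor) / Tc
    down_ph[nm] <- (d - anchor) / Tc
  }
  up_ph["LP"] <- 0
  list(anchor = anchor, period = Tc, up = up_ph, down = down_ph,
       dt = bursts$LP$dt)
}

fold_events <- function(fold) {
  ev <- c(LP_S = fold$up[["LP"]], LP_E = fold$down[["LP"]],
          PY_S = fold$up[["PY"]], PY_E = fold$down[["PY"]],
          PD_S = fold$up[["PD"]], PD_E = fold$down[["PD"]])
  ev
}

has_tie <- function(ev, dt, period) {
  tol <- dt / period
  d <- abs(outer(ev, ev, "-"))
  any(d[upper.tri(d)] < tol)
}

#' Classify the burst-event ordering of a rhythm
#'
#' Folds one cycle anchored at the LP burst onset and returns the order of
#' the six burst boundary events. The ordering is undefined (`NA`) when any
#' neuron has other than one burst per cycle, or when two events coincide
#' within the sample resolution (a tie).
#'
#' @param bursts output of [parse_bursts()].
#' @param period the rhythm period in seconds (see [detect_period()]).
#' @return a character vector of the six event names in temporal order
#'   starting with `LP_S` (with the event phases as attribute `"phases"`),
#'   or `NA` when undefined (with attribute `"reason"`).
#' @export
classify_ordering <- function(bursts, period) {
  fold <- fold_cycle(bursts, period)
  if (is.null(fold)) {
    return(structure(NA_character_, reason = "no single-burst cycle"))
  }
  ev <- fold_events(fold)
  if (has_tie(ev, fold$dt, period)) {
    return(structure(NA_character_, reason = "tie"))
  }
  ord <- names(sort(ev))
  structure(paste(ord, collapse = " "), phases = sort(ev))
}

#' The burst-event ordering conforming to all experimental timing means
#' @return the ordering string `"LP_S PY_S LP_E PY_E PD_S PD_E"`.
#' @export
featured_ordering <- function() "LP_S PY_S LP_E PY_E PD_S PD_E"

#' Evaluate the three pyloric ordering criteria
#'
#' The criteria are: (1) all neurons are silent at the LP burst onset
#' (`gap`); (2) the PY burst begins before the LP burst ends
#' (`PYS_before_LPE`); (3) the LP burst ends before the PY burst ends
#' (`LPE_before_PYE`). Flags are `FALSE` whenever they are undefined (for
#' instance when a neuron lacks exactly one burst per cycle).
#'
#' @inheritParams classify_ordering
#' @param min_gap minimum silent-gap duration in seconds required before
#'   the LP onset for the gap criterion (0 = instantaneous test).
#' @return list with `criteria` (named logical, length 3) and `n_bursting`
#'   (number of neurons crossing the threshold in both directions).
#' @export
evaluate_criteria <- function(bursts, period = NULL, min_gap = 0) {
  n_bursting <- sum(vapply(bursts, function(b) {
    length(b$ups) > 0 && length(b$downs) > 0
  }, logical(1)))
  crit <- c(gap = FALSE, PYS_before_LPE = FALSE, LPE_before_PYE = FALSE)
  fold <- if (!is.null(period)) fold_cycle(bursts, period) else NULL
  if (!is.null(fold) && !has_tie(fold_events(fold), fold$dt, fold$period)) {
    gap <- TRUE
    for (nm in c("PY", "PD")) {
      if (fold$up[[nm]] >= fold$down[[nm]]) gap <- FALSE
      else if (min_gap > 0 &&
               (1 - fold$down[[nm]]) * fold$period < min_gap) gap <- FALSE
    }
    crit["gap"] <- gap
    crit["PYS_before_LPE"] <- fold$up[["PY"]] < fold$down[["LP"]]
    crit["LPE_before_PYE"] <- fold$down[["LP"]] < fold$down[["PY"]]
  }
  list(criteria = crit, n_bursting = n_bursting)
}

permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (k in seq_along(x)) {
    for (rest in permutations(x[-k])) out[[length(out) + 1L]] <- c(x[k], rest)
  }
  out
}

#' Enumerate all burst-event orderings and the pyloric subset
#'
#' With one burst per neuron per cycle and the cycle anchored at the LP
#' burst onset, the remaining five boundary events can occur in `5! = 120`
#' orders (bursts of PY and PD may wrap the cycle boundary, so every
#' permutation is realizable). Each ordering is tagged with the three
#' pyloric criteria; exactly 10 satisfy all three.
#'
#' @return list with `all` (120 ordering strings), `criteria` (data frame
#'   of the three flags per ordering) and `pyloric` (the orderings meeting
#'   all three criteria).
#' @export
enumerate_orderings <- function() {
  rest <- c("PY_S", "LP_E", "PY_E", "PD_S", "PD_E")
  perms <- permutations(rest)
  all <- vapply(perms, function(p) paste(c("LP_S", p), collapse = " "),
                character(1))
  flags <- t(vapply(perms, function(p) {
    pos <- setNames(seq_along(p), p)
    c(gap = unname(pos["PY_S"] < pos["PY_E"] && pos["PD_S"] < pos["PD_E"]),
      PYS_before_LPE = unname(pos["PY_S"] < pos["LP_E"]),
      LPE_before_PYE = unname(pos["LP_E"] < pos["PY_E"]))
  }, logical(3)))
  crit <- as.data.frame(flags)
  crit$ordering <- all
  list(all = all, criteria = crit[, c("ordering", "gap", "PYS_before_LPE",
                                      "LPE_before_PYE")],
       pyloric = all[rowSums(flags) == 3L])
}

#' Duty cycles and burst-start phases
#'
#' Duty cycle \eqn{d_i} is the fraction of the period a neuron spends above
#' the burst threshold; phase \eqn{\phi_i} is the delay of its burst start
#' after the PD burst start, divided by the period (so \eqn{\phi_{PD} = 0}).
#'
#' @inheritParams classify_ordering
#' @return list with `duty` (named, LP/PY/PD) and `phase` (named, LP/PY/PD);
#'   all `NA` when any neuron lacks exactly one burst per cycle.
#' @export
timing_metrics <- function(bursts, period) {
  fold <- fold_cycle(bursts, period)
  if (is.null(fold)) {
    na <- setNames(rep(NA_real_, 3), NEURONS)
    return(list(duty = na, phase = na))
  }
  duty <- (fold$down - fold$up) %% 1
  phase <- (fold$up - fold$up[["PD"]]) %% 1
  list(duty = duty, phase = phase)
}

trapz_mean <- function(time, o, a, b) {
  stopifnot(b > a)
  val <- function(tq) {
    stats::approx(time, o, xout = tq, rule = 2)$y
  }
  inside <- time > a & time < b
  ts <- c(a, time[inside], b)
  vs <- c(val(a), o[inside], val(b))
  sum(diff(ts) * (head(vs, -1) + tail(vs, -1)) / 2) / (b - a)
}

#' Cycle-averaged neuron outputs
#'
#' Trapezoidal mean of each neuron's output over exactly one detected
#' rhythm cycle (anchored at the last full LP cycle); for non-oscillatory
#' trajectories, the mean over a trailing fixed window.
#'
#' @inheritParams parse_bursts
#' @param period rhythm period; `NULL` to detect it from the trajectory.
#' @param window trailing window (seconds) used when no period is defined.
#' @return named numeric of mean outputs, one per neuron.
#' @export
cycle_average <- function(trajectory, period = NULL, window = 50,
                          threshold = 0.5) {
  if (is.null(period)) period <- detect_period(trajectory, threshold)
  t_end <- max(trajectory$time)
  if (is.finite(period)) {
    bursts <- parse_bursts(trajectory, threshold)
    for (nm in NEURONS) {
      cyc <- last_cycle_pair(bursts[[nm]]$ups, period)
      if (!is.null(cyc)) {
        return(vapply(NEURONS, function(n2) {
          trapz_mean(trajectory$time, trajectory$o[, n2], cyc[1], cyc[2])
        }, numeric(1)))
      }
    }
  }
  a <- max(min(trajectory$time), t_end - window)
  vapply(NEURONS, function(nm) {
    trapz_mean(trajectory$time, trajectory$o[, nm], a, t_end)
  }, numeric(1))
}

#' Full rhythm description of a trajectory
#'
#' Runs the whole analysis pipeline — burst parsing, period detection,
#' cycle folding, ordering classification, criteria, timing metrics and
#' cycle averages — and assembles a `rhythm_descriptor`. The default engine
#' is the compiled implementation used inside scans and fitness loops; the
#' pure-R engine composes the exported operations and is cross-checked
#' against it in the test suite.
#'
#' @inheritParams parse_bursts
#' @param config optional [sim_config()] supplying threshold and analysis
#'   tolerances (defaults used when omitted).
#' @param engine `"cpp"` (compiled, default) or `"r"`.
#' @return object of class `rhythm_descriptor`.
#' @export
analyze_rhythm <- function(trajectory, config = NULL,
                           engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (is.null(config)) {
    config <- if (!is.null(trajectory$config)) trajectory$config
              else sim_config(dt = trajectory$time[2] - trajectory$time[1])
  }
  if (engine == "cpp") {
    res <- cpp_analyze(trajectory$time, trajectory$o[, NEURONS],
                       config$threshold, config$nonosc_window,
                       config$period_tol,
                       trajectory$time[2] - trajectory$time[1],
                       config$min_gap)
    ordering <- NA_character_
    if (res$one_per_cycle && !res$tie)
      ordering <- paste(names(sort(res$events)), collapse = " ")
    desc <- list(period = res$period, oscillatory = res$oscillatory,
                 events = res$events, ordering = ordering,
                 n_bursting = res$n_bursting, criteria = res$criteria,
                 duty = res$duty, phase = res$phase, obar = res$obar,
                 one_per_cycle = res$one_per_cycle, tie = res$tie,
                 status = c("silent", "tonic", "bursting")[res$status + 1L],
                 pyloric = res$pyloric)
    names(desc$status) <- NEURONS
    return(structure(desc, class = "rhythm_descriptor"))
  }
  bursts <- parse_bursts(trajectory, config$threshold)
  period <- detect_period(trajectory, config$threshold, config$period_tol)
  ordering <- classify_ordering(bursts, period)
  cr <- evaluate_criteria(bursts, period, config$min_gap)
  tm <- timing_metrics(bursts, period)
  obar <- cycle_average(trajectory, period, config$nonosc_window,
                        config$threshold)
  fold <- fold_cycle(bursts, period)
  one_per_cycle <- !is.null(fold)
  tie <- one_per_cycle && has_tie(fold_events(fold), fold$dt, period)
  events <- if (one_per_cycle) fold_events(fold)[EVENT_NAMES]
            else setNames(rep(NA_real_, 6), EVENT_NAMES)
  pyloric <- cr$n_bursting == 3L && one_per_cycle && !tie &&
    all(cr$criteria)
  structure(list(period = period, oscillatory = is.finite(period),
                 events = events, ordering = as.character(ordering),
                 n_bursting = cr$n_bursting, criteria = cr$criteria,
                 duty = tm$duty, phase = tm$phase, obar = obar,
                 one_per_cycle = one_per_cycle, tie = tie,
                 status = vapply(bursts, `[[`, character(1), "status"),
                 pyloric = pyloric),
            class = "rhythm_descriptor")
}

#' @export
print.rhythm_descriptor <- function(x, ...) {
  cat("<rhythm_descriptor>\n")
  cat("  period   :", if (is.finite(x$period)) sprintf("%.4g s", x$period)
                      else "undefined", "\n")
  cat("  bursting :", x$n_bursting, "of 3\n")
  cat("  ordering :", if (is.na(x$ordering)) "undefined" else x$ordering,
      "\n")
  cat("  criteria :", paste(names(x$criteria), unname(x$criteria),
                            sep = "=", collapse = "  "), "\n")
  cat("  pyloric  :", x$pyloric, "\n")
  cat("  duty     :", paste(sprintf("%s=%.3f", NEURONS, x$duty),
                            collapse = "  "), "\n")
  cat("  obar     :", paste(sprintf("%s=%.3f", NEURONS, x$obar),
                            collapse = "  "), "\n")
  invisible(x)
}
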