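test_that("parse_bursts handles tonic, silent and sinusoidal traces", {
  tm <- seq(0, 3, by = 0.001)
  const_traj <- function(vals) {
    o <- cbind(LP = rep(vals[1], length(tm)), PY = rep(vals[2], length(tm)),
               PD = rep(vals[3], length(tm)))
    list(time = tm, o = o)
  }
  b <- parse_bursts(const_traj(c(0.9, 0.1, 0.5)))
  expect_equal(b$LP$status, "tonic")
  expect_equal(nrow(b$LP$episodes), 0)
  expect_equal(b$PY$status, "silent")
  # output exactly at threshold counts as below
  expect_equal(b$PD$status, "silent")

  # sinusoid 0.5 + 0.4 sin(2 pi t): analytic up-crossings at integers,
  # down-crossings at k + 0.5
  o <- cbind(LP = 0.5 + 0.4 * sin(2 * pi * tm), PY = 0.1, PD = 0.1)
  b <- parse_bursts(list(time = tm, o = o))
  expect_equal(b$LP$status, "bursting")
  expect_equal(nrow(b$LP$episodes), 3)
  expect_lt(max(abs(b$LP$episodes[, "start"] - c(0, 1, 2))), 2 * 0.001)
  expect_lt(max(abs(b$LP$episodes[, "end"] - c(0.5, 1.5, 2.5))), 2 * 0.001)
})

test_that("detect_period finds square waves and rejects fixed points", {
  sq <- square_wave_rhythm(period = 2, n_cycles = 8)
  expect_equal(detect_period(sq), 2, tolerance = 2 * sq$dt / 2)
  fixed <- integrate_ctrnn(zero_weight_circuit(), config = sim_config())
  expect_true(is.na(detect_period(fixed)))
})

test_that("detected period agrees with an autocorrelation oracle", {
  traj <- integrate_ctrnn(helper_oscillator(),
                          network_state(c(LP = 0.1, PY = 0.1, PD = 0)),
                          osc_config())
  T_pkg <- detect_period(traj)
  # oracle: first prominent autocorrelation peak of the LP output
  x <- traj$o[, "LP"] - mean(traj$o[, "LP"])
  ac <- stats::acf(x, lag.max = length(x) - 1, plot = FALSE,
                   demean = FALSE)$acf[, 1, 1]
  n <- length(ac)
  loc <- which(ac[2:(n - 1)] > ac[1:(n - 2)] & ac[2:(n - 1)] > ac[3:n]) + 1
  loc <- loc[ac[loc] > 0.5][1]
  T_acf <- traj$dt * (loc - 1)
  expect_equal(T_pkg, T_acf, tolerance = 0.01 * T_acf)
})

test_that("ordering classification is anchored and rejects violations", {
  sq <- square_wave_rhythm()
  b <- parse_bursts(sq)
  T <- detect_period(sq)
  ord <- classify_ordering(b, T)
  expect_equal(as.character(ord), featured_ordering())

  # shifting the time origin by a non-integer number of periods cannot
  # change the anchored ordering or the metrics
  sq2 <- sq
  keep <- sq2$time >= 0.37
  sq2$time <- sq2$time[keep] - 0.37
  sq2$o <- sq2$o[keep, ]
  b2 <- parse_bursts(sq2)
  expect_equal(as.character(classify_ordering(b2, detect_period(sq2))),
               featured_ordering())
  m1 <- timing_metrics(b, T)
  m2 <- timing_metrics(b2, detect_period(sq2))
  expect_equal(m1$duty, m2$duty, tolerance = 1e-6)
  expect_equal(m1$phase, m2$phase, tolerance = 1e-6)

  # a neuron with two bursts per cycle makes the ordering undefined
  tm <- seq(0, 8, by = 0.001)
  ph <- tm %% 1
  o <- cbind(LP = ifelse(ph < 0.3, 0.9, 0.1),
             PY = ifelse(ph >= 0.2 & ph < 0.5, 0.9, 0.1),
             PD = ifelse((ph >= 0.55 & ph < 0.7) | (ph >= 0.8 & ph < 0.95),
                         0.9, 0.1))
  b3 <- parse_bursts(list(time = tm, o = o))
  expect_true(is.na(classify_ordering(b3, 1)))
})

test_that("criteria flags follow the schematic rhythms", {
  # featured rhythm with phases as in the schematic
  sq <- square_wave_rhythm(phases = c(LP_S = 0, PY_S = 0.2, LP_E = 0.3,
                                      PY_E = 0.5, PD_S = 0.6, PD_E = 0.95))
  b <- parse_bursts(sq)
  cr <- evaluate_criteria(b, detect_period(sq))
  expect_true(all(cr$criteria))
  expect_equal(cr$n_bursting, 3L)
  expect_equal(as.character(classify_ordering(b, detect_period(sq))),
               featured_ordering())

  # PD bursting at the LP onset (wrapping burst) breaks the gap criterion
  sq2 <- square_wave_rhythm(phases = c(LP_S = 0, PY_S = 0.2, LP_E = 0.3,
                                       PY_E = 0.5, PD_S = 0.8, PD_E = 0.1))
  cr2 <- evaluate_criteria(parse_bursts(sq2), detect_period(sq2))
  expect_false(cr2$criteria[["gap"]])
  expect_true(cr2$criteria[["PYS_before_LPE"]])

  # LP ending after PY breaks the third criterion
  sq3 <- square_wave_rhythm(phases = c(LP_S = 0, PY_S = 0.1, PY_E = 0.4,
                                       LP_E = 0.5, PD_S = 0.6, PD_E = 0.9))
  cr3 <- evaluate_criteria(parse_bursts(sq3), detect_period(sq3))
  expect_false(cr3$criteria[["LPE_before_PYE"]])
})

test_that("enumeration yields 120 orderings, 10 of them pyloric", {
  eo <- enumerate_orderings()
  expect_length(eo$all, 120L)
  expect_length(unique(eo$all), 120L)
  expect_length(eo$pyloric, 10L)
  expect_true(featured_ordering() %in% eo$pyloric)
  # closure: every square-wave realization of a pyloric ordering
  # classifies back to it and passes the criteria
  for (ord in eo$pyloric) {
    sq <- square_wave_rhythm(ord)
    b <- parse_bursts(sq)
    T <- detect_period(sq)
    expect_equal(as.character(classify_ordering(b, T)), ord)
    expect_true(all(evaluate_criteria(b, T)$criteria))
  }
  # and a non-pyloric one is rejected by the criteria
  nonp <- setdiff(eo$all, eo$pyloric)[1]
  sqn <- square_wave_rhythm(nonp)
  expect_false(all(evaluate_criteria(parse_bursts(sqn),
                                     detect_period(sqn))$criteria))
})

test_that("timing metrics recover constructed duty cycles and phases", {
  duty <- c(LP = 0.264, PY = 0.348, PD = 0.385)
  ph <- c(LP = 0.35, PY = 0.55, PD = 0)
  sq <- square_wave_rhythm(phases = phases_from_timing(duty, ph),
                           n_cycles = 6)
  b <- parse_bursts(sq)
  T <- detect_period(sq)
  m <- timing_metrics(b, T)
  expect_equal(m$duty, duty, tolerance = 0.01)
  expect_equal(m$phase, ph, tolerance = 0.01)
  expect_equal(m$phase[["PD"]], 0)
})

test_that("cycle averages match constants, duty cycles and quadrature", {
  tm <- seq(0, 10, by = 0.01)
  const <- list(time = tm, o = cbind(LP = rep(0.42, length(tm)),
                                     PY = 0.9, PD = 0.1))
  expect_equal(cycle_average(const)[["LP"]], 0.42, tolerance = 1e-9)

  sq <- square_wave_rhythm(phases = c(LP_S = 0, LP_E = 0.264, PY_S = 0.3,
                                      PY_E = 0.6, PD_S = 0.65, PD_E = 0.9),
                           lo = 0, hi = 1)
  expect_equal(cycle_average(sq)[["LP"]], 0.264, tolerance = 0.01)

  # fixture oscillator versus 10x finer-grid quadrature
  traj <- integrate_ctrnn(helper_oscillator(),
                          network_state(c(LP = 0.1, PY = 0.1, PD = 0)),
                          osc_config())
  fine <- integrate_ctrnn(helper_oscillator(),
                          network_state(c(LP = 0.1, PY = 0.1, PD = 0)),
                          osc_config(dt = 0.001))
  expect_equal(cycle_average(traj), cycle_average(fine), tolerance = 1e-3)
  # bounds: min over cycle <= mean <= max
  ob <- cycle_average(traj)
  for (nm in c("LP", "PY", "PD")) {
    expect_gte(ob[[nm]], min(traj$o[, nm]))
    expect_lte(ob[[nm]], max(traj$o[, nm]))
  }
})

test_that("compiled and pure-R analysis pipelines agree", {
  cases <- list(
    square_wave_rhythm(),
    square_wave_rhythm(phases = c(LP_S = 0, PY_S = 0.2, LP_E = 0.3,
                                  PY_E = 0.5, PD_S = 0.8, PD_E = 0.1)),
    integrate_ctrnn(helper_oscillator(),
                    network_state(c(LP = 0.1, PY = 0.1, PD = 0)),
                    osc_config()),
    integrate_ctrnn(zero_weight_circuit(theta = c(LP = 1, PY = -1, PD = 0)),
                    config = sim_config()))
  for (traj in cases) {
    a <- analyze_rhythm(traj, engine = "cpp")
    b <- analyze_rhythm(traj, engine = "r")
    expect_equal(a$pyloric, b$pyloric)
    expect_equal(a$n_bursting, b$n_bursting)
    expect_equal(a$criteria, b$criteria)
    expect_equal(a$ordering, b$ordering)
    expect_equal(a$period, b$period, tolerance = 1e-9)
    expect_equal(a$obar, b$obar, tolerance = 1e-6)
    expect_equal(a$duty, b$duty, tolerance = 1e-9)
  }
})
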