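test_that("sigma is the logistic function with safe saturation", {
  expect_equal(sigma(0), 0.5)
  x <- c(-7.3, -1, 0.2, 4, 12)
  expect_equal(sigma(x) + sigma(-x), rep(1, length(x)))
  expect_true(all(diff(sigma(seq(-20, 20, by = 0.5))) > 0))
  s <- sigma(-50)
  expect_gt(s, 0)
  expect_lte(s, 1e-20)
  expect_equal(sigma(750), 1) # no overflow, saturates
  expect_equal(logit(sigma(2.3)), 2.3, tolerance = 1e-12)
})

test_that("parameter containers validate their invariants", {
  expect_error(circuit_params(tau = 0.05, theta = 0, w = matrix(0, 3, 3)),
               "time constants")
  expect_error(circuit_params(tau = 1, theta = 17, w = matrix(0, 3, 3)),
               "biases")
  expect_error(circuit_params(tau = 1, theta = 0,
                              w = matrix(c(NA, rep(0, 8)), 3, 3)),
               "finite")
  expect_error(network_state(c(LP = Inf, PY = 0, PD = 0)), "finite")
  expect_error(sim_config(dt = -0.1), "dt")
  expect_error(sim_config(threshold = 1), "threshold")
  # dt must respect the stiffness bound at integration time
  circ <- zero_weight_circuit(tau = 0.1)
  expect_error(integrate_ctrnn(circ, config = sim_config(dt = 0.02)),
               "dt")
  # weight vector form round-trips through the flat key set
  circ2 <- helper_oscillator()
  expect_equal(flat_to_circuit(circuit_to_flat(circ2))$w, circ2$w)
})

test_that("zero-weight network decays exponentially toward the origin", {
  circ <- zero_weight_circuit(tau = c(LP = 0.5, PY = 1, PD = 2))
  traj <- integrate_ctrnn(circ, network_state(c(LP = 1, PY = 1, PD = 1)),
                          sim_config(transient = 0, record = 30, dt = 0.01))
  for (nm in names(circ$tau)) {
    expect_lt(max(abs(traj$y[, nm] - exp(-traj$time / circ$tau[[nm]]))),
              1e-8)
  }
  expect_equal(unname(traj$o[nrow(traj$o), ]), rep(0.5, 3),
               tolerance = 1e-3)
  expect_true(all(traj$o > 0 & traj$o < 1))
})

test_that("RK4 agrees with a fine-step reference over 50 s", {
  circ <- helper_oscillator()
  cfg <- sim_config(dt = 0.01, transient = 0, record = 50)
  y0 <- network_state(c(LP = 0.3, PY = -0.2, PD = 0.1))
  traj <- integrate_ctrnn(circ, y0, cfg)
  # independent route: forward Euler at dt/100
  oracle <- integrate_ctrnn(circ, y0, sim_config(dt = 1e-4, transient = 0,
                                                 record = 50,
                                                 method = "euler"))
  idx <- match(round(traj$time, 6), round(oracle$time, 6))
  expect_false(anyNA(idx))
  expect_lt(max(abs(traj$y - oracle$y[idx, ])), 1e-4)
})

test_that("integrator order matches theory when halving dt", {
  circ <- helper_oscillator()
  y0 <- network_state(c(LP = 0.3, PY = -0.2, PD = 0.1))
  ref <- integrate_ctrnn(circ, y0, sim_config(dt = 5e-4, transient = 0,
                                              record = 10))
  terminal <- function(dt, method) {
    tr <- integrate_ctrnn(circ, y0, sim_config(dt = dt, transient = 0,
                                               record = 10,
                                               method = method))
    tr$y[nrow(tr$y), ]
  }
  ref_y <- ref$y[nrow(ref$y), ]
  e1 <- max(abs(terminal(0.04, "rk4") - ref_y))
  e2 <- max(abs(terminal(0.02, "rk4") - ref_y))
  expect_gt(e1 / e2, 16 * 0.7)
  expect_lt(e1 / e2, 16 * 1.3)
  f1 <- max(abs(terminal(0.04, "euler") - ref_y))
  f2 <- max(abs(terminal(0.02, "euler") - ref_y))
  expect_gt(f1 / f2, 2 * 0.7)
  expect_lt(f1 / f2, 2 * 1.3)
})

test_that("dynamics are invariant under joint time/tau rescaling", {
  circ <- helper_oscillator()
  y0 <- network_state(c(LP = 0.3, PY = -0.2, PD = 0.1))
  a <- integrate_ctrnn(circ, y0, sim_config(dt = 0.01, transient = 0,
                                            record = 20))
  circ2 <- circ
  circ2$tau <- circ$tau * 2
  b <- integrate_ctrnn(circ2, y0, sim_config(dt = 0.02, transient = 0,
                                             record = 40))
  expect_equal(a$y, b$y, tolerance = 1e-10)
})

test_that("integration is deterministic and flags divergence", {
  circ <- helper_oscillator()
  cfg <- sim_config(record = 20)
  a <- integrate_ctrnn(circ, config = cfg)
  b <- integrate_ctrnn(circ, config = cfg)
  expect_identical(a$y, b$y)
})

test_that("equilibrate classifies fixed points and oscillations stably", {
  fixed <- equilibrate(zero_weight_circuit(), config = sim_config())
  expect_equal(fixed$classification, "fixed")
  expect_equal(unname(fixed$state$y), rep(0, 3), tolerance = 1e-10)

  osc <- equilibrate(helper_oscillator(),
                     network_state(c(LP = 0.1, PY = 0.1, PD = 0)),
                     osc_config())
  expect_equal(osc$classification, "oscillatory")
  # classification invariant to doubling the record window
  osc2 <- equilibrate(helper_oscillator(),
                      network_state(c(LP = 0.1, PY = 0.1, PD = 0)),
                      osc_config(record = 400))
  expect_equal(osc2$classification, "oscillatory")
  fixed2 <- equilibrate(zero_weight_circuit(),
                        config = sim_config(record = 100))
  expect_equal(fixed2$classification, "fixed")
})
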