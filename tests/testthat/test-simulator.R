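test_that("step response follows the first-order closed form", {
  net <- single_neuron_net(Cm = 5)
  st <- stimulus_spec("inp", stim_segment("step", duration = 50,
                                          amplitude = 2))
  r <- simulate_network(net, st, T = 50, dt = 0.1)
  expect_equal(unname(r$U[r$t == 5, "n"]), 2 * (1 - exp(-1)),
               tolerance = 1e-7)
  expect_equal(unname(r$U[r$t == 50, "n"]), 2 * (1 - exp(-10)),
               tolerance = 1e-7)
})

test_that("ramp response lags by the membrane capacitance at late times", {
  net <- single_neuron_net(Cm = 5)
  A <- 0.1
  st <- stimulus_spec("inp", stim_segment("ramp", duration = 100, slope = A))
  r <- simulate_network(net, st, T = 100, dt = 0.1)
  expect_equal(unname(r$U[r$t == 100, "n"]), A * (100 - 5),
               tolerance = 1e-6)
})

test_that("halving dt changes the final state negligibly", {
  for (rep in list(design_subtraction(), design_multiplication())) {
    st <- list(stimulus_spec("in1", stim_segment("step", 60, amplitude = 14)),
               stimulus_spec("in2", stim_segment("step", 60, amplitude = 6)))
    a <- simulate_network(rep$network, st, T = 60, dt = 0.2)
    b <- simulate_network(rep$network, st, T = 60, dt = 0.1)
    expect_lt(max(abs(a$U[nrow(a$U), ] - b$U[nrow(b$U), ])), 1e-6)
  }
})

test_that("long-horizon simulation converges to the analytic steady state", {
  for (rep in list(design_addition(), design_division(0.05))) {
    ext <- c(in1 = 9, in2 = 4)
    st <- list(stimulus_spec("in1", stim_segment("constant", 200,
                                                 amplitude = 9)),
               stimulus_spec("in2", stim_segment("constant", 200,
                                                 amplitude = 4)))
    r <- simulate_network(rep$network, st, T = 200, dt = 0.1)
    ss <- steady_state_network(rep$network, ext)
    expect_lt(max(abs(r$U[nrow(r$U), ] - ss)), 1e-6)
  }
})

test_that("stimulus programs evaluate piecewise with local time", {
  st <- stimulus_spec("p", list(
    stim_segment("constant", 10, amplitude = 2),
    stim_segment("ramp", 10, slope = 0.5, offset = 1),
    stim_segment("sine", 10, amplitude = 3, omega = pi / 5),
    stim_segment("zero", 5)))
  expect_equal(stimulus_current(st, c(0, 9.9)), c(2, 2))
  expect_equal(stimulus_current(st, 14), 1 + 0.5 * 4)
  expect_equal(stimulus_current(st, 22.5), 3 * sin(pi / 5 * 2.5))
  expect_equal(stimulus_current(st, c(31, 50)), c(0, 0))
  expect_error(stim_segment("constant", duration = 0), "positive")
})

test_that("noise stimuli are reproducible from their seed", {
  seg <- stim_segment("noise", 50, sd = 1, seed = 7, hold = 2)
  st <- stimulus_spec("p", seg)
  t <- seq(0, 49, by = 0.5)
  expect_identical(stimulus_current(st, t), stimulus_current(st, t))
  st2 <- stimulus_spec("p", stim_segment("noise", 50, sd = 1, seed = 8,
                                         hold = 2))
  expect_false(identical(stimulus_current(st, t), stimulus_current(st2, t)))
  expect_error(stim_segment("noise", 50, sd = 1), "seed")
})

test_that("settled initialisation starts on the network's equilibrium", {
  rep <- design_integrator(0.1, 0.1)
  r <- simulate_network(rep$network, list(), T = 10, dt = 0.25,
                        init = "settled")
  # symmetric equilibrium of the default integrator: U1 = U2 = sqrt(300)-10
  Ueq <- sqrt(300) - 10
  expect_equal(unname(r$U[1, ]), c(Ueq, Ueq), tolerance = 1e-6)
  expect_lt(max(abs(r$U[nrow(r$U), ] - r$U[1, ])), 1e-9)
})

test_that("ramp plateaus measure the differentiator gain", {
  # small-signal regime so the subtraction stage's activity-dependent
  # denominator stays near its resting value
  kd <- 0.5; taud <- 0.6; ks <- 0.1
  rep <- design_differentiator(k_d = kd, tau_d = taud, k_syn_out = ks)
  A <- 2e-4
  st <- stimulus_spec("input", stim_segment("ramp", 9000, slope = A))
  r <- suppressWarnings(simulate_network(rep$network, st, T = 9000,
                                         dt = 0.5))
  m <- measure_ramp_step_response(r, "post", st, tau_d = 1000 * taud)
  expect_true(m$reliable)
  expect_equal(m$plateau, ks * 1000 * kd * A, tolerance = 0.02)
  # zero slope gives a zero plateau
  st0 <- stimulus_spec("input", stim_segment("ramp", 9000, slope = 0))
  r0 <- suppressWarnings(simulate_network(rep$network, st0, T = 9000,
                                          dt = 0.5))
  m0 <- measure_ramp_step_response(r0, "post", st0, tau_d = 1000 * taud)
  expect_equal(m0$plateau, 0, tolerance = 1e-9)
  # a segment shorter than (settle+1)*tau_d is flagged unreliable
  st_short <- stimulus_spec("input", stim_segment("ramp", 1000, slope = A))
  r_short <- suppressWarnings(simulate_network(rep$network, st_short,
                                               T = 1000, dt = 0.5))
  m_short <- measure_ramp_step_response(r_short, "post", st_short,
                                        tau_d = 1000 * taud)
  expect_false(m_short$reliable)
})

test_that("integration-rate measurement recovers the designed mean rate", {
  rep <- design_integrator(0.1, 0.1)
  u <- 0.1
  st <- stimulus_spec("u", stim_segment("step", 200, amplitude = u))
  r <- simulate_network(rep$network, st, T = 200, dt = 0.25,
                        init = "settled")
  m <- measure_integration_rate(r, "u1", 50, 150, R = 20)
  expect_false(m$truncated)
  expect_gt(m$slope, rep$derived$k_i_min * u)
  expect_lt(m$slope, rep$derived$k_i_max * u)
  # doubling the drive doubles the slope while the state stays near the
  # same stretch of the attractor (short window, small drive: k_i is
  # state-dependent, so linearity only holds at fixed (a, b))
  st2 <- stimulus_spec("u", stim_segment("step", 200, amplitude = 2 * u))
  r2 <- simulate_network(rep$network, st2, T = 200, dt = 0.25,
                         init = "settled")
  m_s <- measure_integration_rate(r, "u1", 20, 80, R = 20)
  m2 <- measure_integration_rate(r2, "u1", 20, 80, R = 20)
  expect_equal(m2$slope / m_s$slope, 2, tolerance = 0.03)
  # zero drive: marginal equilibrium, no slope
  r0 <- simulate_network(rep$network, list(), T = 200, dt = 0.25,
                         init = "settled")
  m0 <- measure_integration_rate(r0, "u1", 50, 150, R = 20)
  expect_equal(m0$slope, 0, tolerance = 1e-10)
})

test_that("simulator guards its preconditions", {
  net <- single_neuron_net(Cm = 5)
  expect_warning(simulate_network(net, list(), T = 5, dt = 2), "dt")
  r0 <- simulate_network(net, list(), T = 0)
  expect_identical(nrow(r0$U), 0L)
  expect_error(simulate_network(net, stimulus_spec("nope",
                                                   stim_segment("zero", 1)),
                                T = 1),
               "unknown port")
})
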