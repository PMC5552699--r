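test_that("synaptic conductance is piecewise linear and clamped", {
  s <- synapse_spec("a", "b", gs = 0.115, dEs = 194, R = 20)
  expect_identical(synaptic_conductance(s, -5), 0)
  expect_identical(synaptic_conductance(s, 30), 0.115)
  expect_equal(synaptic_conductance(s, 10), 0.0575)
  # clamp property over random synapses and activations
  set.seed(42)
  for (i in 1:25) {
    syn <- synapse_spec("a", "b", gs = runif(1, 0, 25),
                        dEs = runif(1, -100, 300), R = sample(c(10, 20, 40), 1),
                        Elo = runif(1, -5, 5))
    U <- runif(40, -100, 100)
    g <- synaptic_conductance(syn, U)
    expect_true(all(g >= 0 & g <= syn$gs))
  }
})

test_that("synaptic current sign follows the reversal potential", {
  # dEs >= R: always depolarizing over U_post in [0, R); dEs <= 0: always
  # hyperpolarizing over (0, R]
  R <- 20
  exc <- synapse_spec("a", "b", gs = 0.5, dEs = R, R = R)
  inh <- synapse_spec("a", "b", gs = 0.5, dEs = 0, R = R)
  U_pre <- seq(0.5, R, length.out = 9)
  for (U_post in seq(0, R - 0.5, length.out = 9)) {
    I <- synaptic_conductance(exc, U_pre) * (exc$dEs - U_post)
    expect_true(all(I >= 0))
  }
  for (U_post in seq(0.5, R, length.out = 9)) {
    I <- synaptic_conductance(inh, U_pre) * (inh$dEs - U_post)
    expect_true(all(I <= 0))
  }
})

test_that("network construction validates references and names", {
  n <- list(neuron_spec("a"), neuron_spec("b"))
  expect_error(network_spec(list(neuron_spec("a"), neuron_spec("a"))),
               "unique")
  expect_error(network_spec(n, list(synapse_spec("a", "zzz", 1, 0, 20))),
               "undeclared neuron 'zzz'")
  expect_error(network_spec(n, inputs = list(p = "nope")),
               "undeclared neuron 'nope'")
  expect_error(neuron_spec("x", Cm = 0), "Cm")
  expect_error(synapse_spec("a", "b", gs = -1, dEs = 0, R = 20), "gs")
  expect_error(synapse_spec("a", "b", gs = 1, dEs = 0, R = 0), "R")
})

test_that("membrane derivative matches the shifted leaky-integrator equation", {
  net <- single_neuron_net(Cm = 5)
  expect_equal(neuron_derivative(net, c(n = 0), c(inp = 5))[["n"]], 1)
  expect_equal(neuron_derivative(net, c(n = 5), c(inp = 5))[["n"]], 0)
  # transmission fixed point: with gs tuned for k_syn = 1 the post neuron
  # at U = R under a fully active presynaptic input has zero drift
  gs <- tune_transmission(1, 20, 194)
  net2 <- network_spec(
    list(neuron_spec("pre"), neuron_spec("post")),
    list(synapse_spec("pre", "post", gs, 194, 20)),
    inputs = list(inp = "pre"))
  dU <- neuron_derivative(net2, c(pre = 20, post = 20), c(inp = 20))
  expect_equal(dU[["post"]], 0, tolerance = 1e-12)
  expect_error(neuron_derivative(net2, c(pre = 0)), "missing")
})

test_that("single-neuron equilibrium matches hand evaluation", {
  expect_equal(steady_state_neuron(NULL, Iapp = 5), 5)
  expect_equal(
    steady_state_neuron(data.frame(gs = 0.114943, dEs = 194, U_pre = 20,
                                   R = 20)),
    20, tolerance = 1e-4)
  expect_equal(
    steady_state_neuron(data.frame(gs = 0.114943, dEs = 194, U_pre = 10,
                                   R = 20)),
    eq13_by_hand(0.114943, 194, 10, 20))
  # presynaptic activations outside [0, R] are clamped before entering
  expect_equal(
    steady_state_neuron(data.frame(gs = 1, dEs = 100, U_pre = 35, R = 20)),
    steady_state_neuron(data.frame(gs = 1, dEs = 100, U_pre = 20, R = 20)))
})

test_that("network steady state satisfies the drift equation", {
  # feedforward designs solved in topological order
  for (rep in list(design_addition(), design_subtraction(),
                   design_division(0.05), design_multiplication())) {
    ext <- c(in1 = 13, in2 = 7)
    ss <- steady_state_network(rep$network, ext)
    expect_true(attr(ss, "converged"))
    expect_lt(max(abs(neuron_derivative(rep$network, ss, ext))), 1e-6)
  }
  expect_equal(
    unname(steady_state_network(design_subtraction()$network,
                                c(in1 = 20, in2 = 20))[["post"]]),
    0, tolerance = 1e-9)
})

test_that("cyclic networks are solved by damped fixed-point iteration", {
  # weak mutual excitation: contractive, has a unique equilibrium
  gs <- tune_transmission(0.3, 20, 194)
  net <- network_spec(
    list(neuron_spec("a"), neuron_spec("b")),
    list(synapse_spec("a", "b", gs, 194, 20),
         synapse_spec("b", "a", gs, 194, 20)),
    inputs = list(pa = "a"))
  ss <- steady_state_network(net, c(pa = 10))
  expect_true(attr(ss, "converged"))
  expect_lt(max(abs(neuron_derivative(net, ss, c(pa = 10)))), 1e-6)
  # the driven integrator leaves the marginal operating range and settles
  # where a synapse saturates; the solver must still find that equilibrium
  rep <- design_integrator(0.1, 0.1)
  ss2 <- steady_state_network(rep$network, c(u = 1))
  expect_true(attr(ss2, "converged"))
  expect_lt(max(abs(neuron_derivative(rep$network, ss2, c(u = 1)))), 1e-6)
  # and when the iteration budget is exhausted, failure is reported with a
  # residual, never silently
  expect_warning(ss3 <- steady_state_network(rep$network, c(u = 1),
                                             max_iter = 3),
                 "not converge")
  expect_false(attr(ss3, "converged"))
  expect_true(is.finite(attr(ss3, "residual")))
})

test_that("sensor mapping is affine onto [0, R] and invertible", {
  m <- sensor_map(-90, 90, R = 20)
  expect_equal(map_sensor_to_current(m, -90), 0)
  expect_equal(map_sensor_to_current(m, 90), 20)
  expect_equal(map_sensor_to_current(m, 0), 10)
  theta <- seq(-90, 90, length.out = 31)
  back <- map_activity_to_command(m, map_sensor_to_current(m, theta))
  expect_equal(back, theta, tolerance = 1e-12)
  expect_warning(I <- map_sensor_to_current(m, 120), "clamping")
  expect_equal(I, 20)
  expect_error(sensor_map(5, 5, 20), "degenerate")
})

test_that("absolute reversal potentials convert to the shifted convention", {
  expect_equal(relative_reversal(134, -60), 194)
  expect_equal(relative_reversal(-100, -60), -40)
})
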