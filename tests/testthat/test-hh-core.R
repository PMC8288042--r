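test_that("steady_state evaluates the sigmoid and saturates safely", {
  g <- gate_spec("g", ss = c(0.1, 4), tau = list(c(1, 0, 0)))
  expect_equal(steady_state(g, -40), 0.5)            # exponent exactly zero
  expect_equal(steady_state(g, 1e6), 0)              # saturation, no NaN
  expect_equal(steady_state(g, -1e6), 1)
  g2 <- gate_spec("g2", ss = c(-0.1, -3), tau = list(c(1, 0, 0)))
  expect_equal(steady_state(g2, 0), 0.9525741268224332, tolerance = 1e-12)
  # monotone: decreasing iff a1 > 0
  V <- seq(-120, 80, by = 1)
  expect_true(all(diff(steady_state(g, V)) < 0))
  expect_true(all(diff(steady_state(g2, V)) > 0))
})

test_that("time_constant is the reciprocal summed-exponential rate", {
  g1 <- gate_spec("a", ss = c(0.1, 0), tau = list(c(1, 0, 0)))
  expect_equal(time_constant(g1, -30), 1.0)
  g2 <- gate_spec("b", ss = c(0.1, 0), tau = list(c(1, 0, 0), c(1, 0, 0)))
  expect_equal(time_constant(g2, 55), 0.5)
  g3 <- gate_spec("c", ss = c(0.1, 0), tau = list(c(2, 0.1, 0)))
  expect_equal(time_constant(g3, 10), 1 / (2 * exp(1)), tolerance = 1e-12)
  # positivity is a construction invariant
  expect_error(gate_spec("d", ss = c(0.1, 0),
                         tau = list(c(1, 0, 0), c(-1, 0, 0))),
               "underflowed")
})

test_that("gate_derivative is first-order relaxation with its fixed point", {
  g <- gate_spec("g", ss = c(0.1, 4), tau = list(c(0.5, 0, 0)))
  V <- -52
  xs <- steady_state(g, V)
  expect_equal(gate_derivative(xs, g, V), 0)
  g2 <- gate_spec("h", ss = c(0, 0), tau = list(c(0.5, 0, 0)))  # x_inf = 0.5, tau = 2
  expect_equal(gate_derivative(0, g2, 0), 0.25)
})

test_that("nernst reproduces the physiological reversal potentials", {
  expect_equal(nernst(1, 5, 5), 0)
  expect_equal(nernst(1, 5.4, 139.275), -86.8566824914, tolerance = 1e-10)
  expect_equal(nernst(1, 140, 10.735), 68.6326095992, tolerance = 1e-10)
  # divalent halves the slope
  expect_equal(nernst(2, 1.5, 1.5e-4), nernst(1, 1.5, 1.5e-4) / 2)
  expect_error(nernst(1, -1, 5), "positive")
  expect_error(nernst(3, 5, 5), "valence")
})

test_that("channel_current has the conductance-gates-driving-force product form", {
  ch <- channel_spec("CaL", g = 6.2894, gates = list(c("l", 1)), E_fixed = 65)
  expect_equal(channel_current(ch, c(l = 1), V = 66, E = 65), 6.2894)
  expect_equal(channel_current(ch, c(l = 1), V = 65, E = 65), 0)
  expect_equal(channel_current(ch, c(l = 0), V = 0, E = 65), 0)
  # linear in driving force and in conductance
  i1 <- channel_current(ch, c(l = 0.5), V = 75, E = 65)
  i2 <- channel_current(ch, c(l = 0.5), V = 85, E = 65)
  expect_equal(i2, 2 * i1)
  ch2 <- channel_spec("CaL", g = 2 * 6.2894, gates = list(c("l", 1)), E_fixed = 65)
  expect_equal(channel_current(ch2, c(l = 0.5), V = 75, E = 65), 2 * i1)
  expect_error(channel_current(ch, c(m = 1), V = 0, E = 65), "gate 'l'")
})

test_that("membrane_rhs assembles currents, gates and the applied current", {
  toy <- toy_fixture()$model
  # no channels, no applied current: V rides the readout only
  d <- membrane_rhs(0, toy$initial_state, toy)
  expect_equal(d[1], 100 * d[2])
  # applied current divided by capacitance
  m <- cell_model("bare", gates = list(gate_spec("x", c(0, 0), list(c(1, 0, 0)))),
                  channels = list(), capacitance = 100,
                  initial_state = c(V = -72, x = 0.5))
  expect_equal(membrane_rhs(0, m$initial_state, m, i_app = 528)[1], 5.28)
  expect_equal(membrane_rhs(0, m$initial_state, m)[1], 0)
  expect_error(membrane_rhs(0, m$initial_state, m, tau_scale = c(zz = 1.1)),
               "zz")
})

test_that("cell_model validates its structural invariants", {
  g <- gate_spec("x", c(0, 0), list(c(1, 0, 0)))
  expect_error(cell_model("m", list(g), list(), 1, c(V = 0)), "state layout")
  expect_error(cell_model("m", list(g, g), list(), 1, c(V = 0, x = 0.1)),
               "duplicate")
  bad <- channel_spec("Na", 1, gates = list(c("zz", 1)), E_fixed = 50)
  expect_error(cell_model("m", list(g), list(bad), 1, c(V = 0, x = 0.1)),
               "undefined gate 'zz'")
})
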