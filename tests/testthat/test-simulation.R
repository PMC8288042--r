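test_that("stimulus protocols validate and evaluate piecewise", {
  expect_error(stimulus_protocol(onset = 10, total_time = 5), "total_time")
  expect_error(stimulus_protocol(mode = "pulse"), "duration")
  pr <- stimulus_protocol(amplitude = 528, onset = 60, duration = 7,
                          mode = "pulse", total_time = 100)
  f <- apcontrib:::iapp_fun(pr)
  expect_equal(f(c(0, 60, 65, 67.1, 99)), c(0, 528, 528, 0, 0))
})

test_that("a current-free model holds its initial potential", {
  m <- cell_model("hold", gates = list(gate_spec("x", c(0, 0), list(c(1, 0, 0)))),
                  channels = list(), capacitance = 1,
                  initial_state = c(V = -55, x = 0.2))
  tr <- simulate_model(m, NULL, solver_options(output_dt = 0.1),
                       window = c(0, 10))
  expect_lt(max(abs(tr$mat[, "V"] + 55)), 1e-9)
  # gate relaxes towards 0.5 meanwhile
  expect_gt(tr$mat[nrow(tr$mat), "x"], 0.49)
})

test_that("clamped-voltage gate relaxation matches the closed form", {
  sq <- clamp_model(squid_axon_model(), V = -30)
  opts <- solver_options(rtol = 1e-10, atol = 1e-12, output_dt = 0.01)
  tr <- simulate_model(sq, NULL, opts, window = c(0, 15))
  for (g in c("m", "h", "n")) {
    spec <- sq$gates[[g]]
    xs <- steady_state(spec, -30)
    tau <- time_constant(spec, -30)
    x0 <- sq$initial_state[[g]]
    closed <- xs + (x0 - xs) * exp(-tr$t / tau)
    expect_lt(max(abs(tr$mat[, g] - closed)), 1e-6)
  }
})

test_that("trajectories are uniform, finite and bounded gates stay in [0,1]", {
  fx <- squid_fixture()
  tr <- fx$ref
  expect_true(all(abs(diff(tr$t) - tr$dt) < 1e-9))
  expect_false(any(!is.finite(tr$mat)))
  for (g in names(fx$model$gates)) {
    x <- tr$mat[, g]
    expect_true(all(x >= 0 & x <= 1))
  }
})

test_that("solver tolerance refinement leaves the action potential unchanged", {
  fx <- squid_fixture()
  opts2 <- solver_options(rtol = fx$options$rtol / 2, atol = fx$options$atol / 2,
                          output_dt = fx$options$output_dt)
  tr2 <- simulate_model(fx$model, fx$protocol, opts2)
  expect_lt(max(abs(tr2$mat[, "V"] - fx$ref$mat[, "V"])), 0.01)
})

test_that("resample reproduces its own grid, linear and smooth series", {
  t <- seq(0, 10, by = 0.05)
  lin <- cbind(V = 3 + 2 * t, w = 1 - 0.5 * t)
  traj <- apcontrib:::new_trajectory(t, lin, "lin", NULL,
                                     solver_options(output_dt = 0.05), 3)
  expect_identical(resample(traj, 0.05), traj)
  r <- resample(traj, 0.013)
  expect_lt(max(abs(r$mat[, "V"] - (3 + 2 * r$t))), 1e-9)
  sine <- cbind(V = sin(t))
  straj <- apcontrib:::new_trajectory(t, sine, "sin", NULL,
                                      solver_options(output_dt = 0.05), 0)
  r2 <- resample(straj, 0.005)
  expect_lt(max(abs(r2$mat[, "V"] - sin(r2$t))), 1e-6)
  expect_error(resample(traj, 100), "span")
})

test_that("state interpolation restarts match the stored grid", {
  fx <- toy_fixture()
  s <- state_at(fx$ref, fx$ref$t[10])
  expect_equal(unname(s), unname(fx$ref$mat[10, ]))
  mid <- state_at(fx$ref, fx$ref$t[10] + fx$ref$dt / 3)
  expect_true(all(is.finite(mid)))
  expect_error(state_at(fx$ref, max(fx$ref$t) + 1), "span")
})
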