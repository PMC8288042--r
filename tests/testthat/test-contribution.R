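test_that("threshold fixture has unit contribution for every delta", {
  fx <- toy_fixture()
  D <- fx$info$duration
  for (delta in c(0.01, 0.1, 0.6)) {
    r <- contribution_interval(fx$model, fx$ref, "x", c(0, D), delta,
                               tight_opts())
    expect_lt(abs(r$C - 1), 1e-6, label = paste("delta =", delta))
  }
})

test_that("a gate decoupled from every current contributes nothing", {
  fx <- toy_fixture()
  m2 <- add_null_gate(fx$model)
  ref2 <- simulate_model(m2, NULL, tight_opts(),
                         window = c(0, 3 * fx$info$duration))
  r <- contribution_interval(m2, ref2, "znull", c(0, fx$info$duration), 0.1,
                             tight_opts())
  expect_lt(abs(r$C), 1e-9)
})

test_that("the identity perturbation returns the reference duration exactly", {
  fx <- toy_fixture()
  D <- fx$info$duration
  expect_identical(perturbed_duration(fx$model, fx$ref, "x", c(0, D), 0), D)
  # and a re-integrated tiny perturbation stays within solver tolerance of
  # the proportional prediction
  Dp <- perturbed_duration(fx$model, fx$ref, "x", c(0, D), 1e-6, tight_opts())
  expect_equal(Dp, D * (1 + 1e-6), tolerance = 1e-9)
})

test_that("scaling tau scales the threshold fixture's event time exactly", {
  m1 <- toy_threshold_model(tau = 2)
  m2 <- toy_threshold_model(tau = 2.2)
  expect_equal(attr(m2, "toy")$duration, 1.1 * attr(m1, "toy")$duration)
})

test_that("aggregation rules follow their defining algebra", {
  res <- data.frame(gate = "x", t_start = c(0, 1), t_end = c(1, 2),
                    D = c(1, 1), D_perturbed = c(1.03, 0.97),
                    delta = 0.1, C = c(0.3, -0.3))
  expect_equal(aggregate_summed(res), 0)
  expect_equal(aggregate_pooled(res), 0)
  one <- res[1, ]
  expect_equal(aggregate_summed(one), aggregate_pooled(one))
  # duration weighting: durations (1, 9), contributions (1, 0) -> 0.1
  res2 <- data.frame(gate = "x", t_start = c(0, 1), t_end = c(1, 10),
                     D = c(1, 9), D_perturbed = c(2, 9), delta = 1)
  res2$C <- ((res2$D_perturbed - res2$D) / res2$D) / res2$delta
  expect_equal(res2$C, c(1, 0))
  expect_equal(aggregate_pooled(res2), 0.1)
  # equal durations: pooled = mean of the two C values
  res3 <- res
  expect_equal(aggregate_pooled(res3), mean(res3$C))
  expect_error(aggregate_summed(res[0, ]), "no epoch")
  res4 <- res; res4$gate <- c("x", "y")
  expect_error(aggregate_pooled(res4), "share")
})

test_that("the sign convention enumerates as stated", {
  # positive reversal: same direction of gate and potential => positive
  expect_equal(expected_sign("Na", "rising", "depolarizing", "positive"), "+")
  expect_equal(expected_sign("Ca", "falling", "repolarizing", "positive"), "+")
  expect_equal(expected_sign("Na", "falling", "depolarizing", "positive"), "-")
  expect_equal(expected_sign("Ca", "rising", "repolarizing", "positive"), "-")
  # potassium mirrors every case
  expect_equal(expected_sign("K", "rising", "depolarizing", "negative"), "-")
  expect_equal(expected_sign("K", "falling", "depolarizing", "negative"), "+")
  expect_equal(expected_sign("K", "rising", "repolarizing", "negative"), "+")
  expect_equal(expected_sign("K", "falling", "repolarizing", "negative"), "-")
})

test_that("summed, pooled and direct whole-region measurements agree on a single epoch", {
  # toy: the whole event interval is one epoch
  fx <- toy_fixture()
  D <- fx$info$duration
  ep <- data.frame(gate = "x", k = 1, phase = 0, t_start = 0, t_end = D,
                   V_start = 0, V_end = fx$info$V_threshold, increasing = TRUE)
  res <- contribution_epochs(fx$model, fx$ref, ep, 0.1, tight_opts())
  direct <- contribution_interval(fx$model, fx$ref, "x", c(0, D), 0.1,
                                  tight_opts())
  expect_lt(abs(aggregate_summed(res) - direct$C), 1e-6 * abs(direct$C))
  expect_lt(abs(aggregate_pooled(res) - direct$C), 1e-6 * abs(direct$C))
  # squid: a genuine epoch from the segmentation
  sq <- squid_fixture()
  eps <- build_epochs(sq$ref, "n", sq$phases)
  one <- eps[which.max(eps$t_end - eps$t_start), , drop = FALSE]
  res2 <- contribution_epochs(sq$model, sq$ref, one, 0.1, sq$options)
  direct2 <- contribution_interval(sq$model, sq$ref, "n",
                                   c(one$t_start, one$t_end), 0.1, sq$options)
  expect_lt(abs(aggregate_summed(res2) - direct2$C),
            1e-6 * max(abs(direct2$C), 1e-3))
  expect_lt(abs(aggregate_pooled(res2) - direct2$C),
            1e-6 * max(abs(direct2$C), 1e-3))
})

test_that("full analysis of the squid fixture has the expected structure and signs", {
  fx <- squid_fixture()
  cfg <- analysis_config(delta = 0.1, options = fx$options,
                         criteria = phase_criteria(min_amplitude = 60))
  tab <- run_full_analysis(fx$model, fx$protocol, cfg)
  expect_s3_class(tab, "contribution_table")
  expect_setequal(rownames(tab), names(fx$model$gates))
  expect_equal(ncol(tab), 4 + 16 + 3)
  expect_length(attr(tab, "errors"), 0)
  # sodium activation speeds the upstroke: slowing it prolongs depolarisation
  expect_gt(tab["m", "P0"], 0)
  # every IoI value is defined for analysed gates
  expect_false(anyNA(tab[, grep("IoI", colnames(tab))]))
  diag <- attr(tab, "diagnostics")
  expect_true(is.data.frame(diag))
  expect_equal(diag$expected[diag$gate == "m" & diag$phase == 0], "+")
})

test_that("a null gate appended to the squid model measures zero everywhere", {
  fx <- squid_fixture()
  m2 <- add_null_gate(fx$model, "zeta", x_inf = 0.3, tau = 2)
  # tight tolerances: near-tangential epoch ends amplify solver-level time
  # jitter, which is exactly what the null gate exposes
  opts <- solver_options(rtol = 1e-11, atol = 1e-13, output_dt = 0.01)
  ref2 <- simulate_model(m2, fx$protocol, opts)
  ph <- segment_phases(ref2, phase_criteria(min_amplitude = 60))
  ep <- build_epochs(ref2, "zeta", ph)
  res <- contribution_epochs(m2, ref2, ep, 0.1, opts)
  expect_lt(max(abs(res$C)), 1e-5)
})
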