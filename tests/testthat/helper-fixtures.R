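# Shared fixtures; heavy objects are computed once per test run and cached.
.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

tight_opts <- function(dt = 0.005)
  solver_options(rtol = 1e-12, atol = 1e-14, output_dt = dt)

toy_fixture <- function() memo("toy", {
  m <- toy_threshold_model()
  info <- attr(m, "toy")
  ref <- simulate_model(m, NULL, tight_opts(), window = c(0, 3 * info$duration))
  list(model = m, info = info, ref = ref)
})

squid_fixture <- function() memo("squid", {
  m <- squid_axon_model()
  pr <- stimulus_protocol(amplitude = 12, onset = 5, total_time = 60,
                          mode = "constant")
  opts <- solver_options(output_dt = 0.01)
  ref <- simulate_model(m, pr, opts)
  ph <- segment_phases(ref, phase_criteria(min_amplitude = 60))
  list(model = m, protocol = pr, options = opts, ref = ref, phases = ph)
})

rat_fixture <- function() memo("rat", {
  m <- build_rat_model()
  d <- rat_analysis_defaults()
  opts <- solver_options(output_dt = 0.001)
  ref <- simulate_model(m, d$protocol, opts, window = d$window)
  ph <- segment_phases(ref, d$criteria)
  list(model = m, defaults = d, options = opts, ref = ref, phases = ph)
})

rat_table <- function() memo("rat_table", {
  fx <- rat_fixture()
  cfg <- analysis_config(delta = 0.1, options = fx$options,
                         criteria = fx$defaults$criteria,
                         window = fx$defaults$window,
                         gates = c("n", "nf", "ns", "l", "kt", "s"))
  run_full_analysis(fx$model, fx$defaults$protocol, cfg, ref = fx$ref)
})

# phase-level contribution matrix for a subset of gates at a given output
# dt; both grids use the same tight window around the AP so the comparison
# isolates the output-grid effect
rat_phase_contributions <- function(dt, gates) {
  key <- paste0("ratC_", dt)
  memo(key, {
    fx <- rat_fixture()
    opts <- solver_options(output_dt = dt)
    ref <- simulate_model(fx$model, fx$defaults$protocol, opts,
                          window = c(64, 127))
    ph <- segment_phases(ref, fx$defaults$criteria)
    out <- matrix(NA_real_, length(gates), 4,
                  dimnames = list(gates, paste0("P", 0:3)))
    for (g in gates) {
      ep <- build_epochs(ref, g, ph)
      res <- contribution_epochs(fx$model, ref, ep, 0.1, opts)
      for (p in 0:3) out[g, p + 1] <- sum(res$C[res$phase == p])
    }
    list(C = out, phases = ph)
  })
}
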