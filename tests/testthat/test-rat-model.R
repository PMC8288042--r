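test_that("the bundled rat model carries the tabulated parameters and state", {
  fx <- rat_fixture()
  m <- fx$model
  expect_length(m$state_layout, 30)
  expect_length(m$gates, 16)
  expect_equal(m$initial_state[["V"]], -72)
  g <- vapply(m$channels, function(ch) ch$g, numeric(1))
  names(g) <- vapply(m$channels, function(ch) ch$name, character(1))
  expect_equal(g[["Na"]], 1.0044e+3)
  expect_equal(g[["CaL"]], 6.2894)
  expect_equal(g[["K1"]], 6)
  expect_equal(m$concentrations$K_o, 5.4)
  expect_equal(m$concentrations$Ca_o, 1.5)
  expect_equal(m$initial_state[["PO1"]], 4.327e-4)
  # the right-hand side is finite at the tabulated state
  expect_true(all(is.finite(membrane_rhs(0, m$initial_state, m))))
})

test_that("gating steady states at -72 mV reproduce the tabulated rest", {
  m <- rat_fixture()$model
  init <- rat_initial_state()
  pinned <- setdiff(names(m$gates), c("l", "Cai"))  # l uses an explicit midpoint
  for (g in pinned)
    expect_equal(steady_state(m$gates[[g]], -72), unname(init[[g]]),
                 tolerance = 1e-10, label = paste("gate", g))
  cai <- m$gates[["Cai"]]
  expect_equal(1 / (1 + exp(cai$ss[1] * init[["Ca_ss"]] + cai$ss[2])),
               0.99, tolerance = 1e-10)
})

test_that("calcium fluxes vanish at their equilibria and reject bad input", {
  p <- rat_model_parameters()
  st <- rat_initial_state()
  st[["Ca_JSR"]] <- st[["Ca_NSR"]] <- 0.066
  fx <- calcium_fluxes(st, p)
  expect_equal(fx$Jtr, 0)
  # buffer binding equilibrium: k+ * Ca * (Btot - B) = k- * B
  ca <- p$ca
  st2 <- rat_initial_state()
  st2[["HTRPNCa"]] <- ca$khtrpn_p * st2[["Ca_i"]] * ca$HTRPNtot /
    (ca$khtrpn_p * st2[["Ca_i"]] + ca$khtrpn_m)
  expect_equal(calcium_fluxes(st2, p)$dHTRPNCa, 0, tolerance = 1e-15)
  st3 <- rat_initial_state(); st3[["Ca_i"]] <- -1e-6
  expect_error(calcium_fluxes(st3, p), "Ca_i")
})

test_that("total calcium changes only through trans-sarcolemmal transport", {
  fx <- rat_fixture()
  m <- fx$model
  tr <- fx$ref
  ca <- m$params$ca
  cons <- m$constants
  sel <- seq(1, nrow(tr$mat), by = 20)   # 0.02 ms sampling
  st <- tr$mat[sel, , drop = FALSE]
  bound <- function(conc, tot, km) tot * conc / (km + conc)
  total <- ca$Vmyo * (st[, "Ca_i"] + bound(st[, "Ca_i"], ca$CMDNtot, ca$KmCMDN) +
                        st[, "HTRPNCa"] + st[, "LTRPNCa"]) +
    ca$Vss * (st[, "Ca_ss"] + bound(st[, "Ca_ss"], ca$CMDNtot, ca$KmCMDN)) +
    ca$VJSR * (st[, "Ca_JSR"] + bound(st[, "Ca_JSR"], ca$CSQNtot, ca$KmCSQN)) +
    ca$VNSR * st[, "Ca_NSR"]
  # membrane Ca2+ current at each sample (pA): CaL + CaT + BCa + pump - 2 NCX
  ECa <- nernst(2, m$concentrations$Ca_o, st[, "Ca_i"], cons)
  ICaL <- m$params$g[["CaL"]] * st[, "l"] * st[, "lf"] * st[, "ls"] *
    st[, "Cai"] * (st[, "V"] - m$params$E_fixed[["CaL"]])
  ICaT <- m$params$g[["CaT"]] * st[, "ct"] * st[, "cti"] *
    (st[, "V"] - m$params$E_fixed[["CaT"]])
  IBCa <- m$params$g[["BCa"]] * (st[, "V"] - ECa)
  pump <- t(vapply(seq_len(nrow(st)), function(i)
    apcontrib:::rat_pump_currents(st[i, "V"], st[i, ], m$params$pumps,
                                  m$concentrations, cons),
    c(INaK = 0, INaCa = 0, ICaP = 0)))
  flux <- -(ICaL + ICaT + IBCa + pump[, "ICaP"] - 2 * pump[, "INaCa"]) /
    (2 * cons$F)
  dtg <- tr$dt * 20
  influx <- cumsum((flux[-1] + flux[-length(flux)]) / 2) * dtg
  drift <- (total[-1] - total[1]) - influx
  # conservation to discretisation accuracy, measured against the size of
  # the calcium movements themselves
  scale <- max(abs(influx), max(total) - min(total))
  expect_lt(max(abs(drift)), 1e-3 * scale)
})

test_that("the dynamics hook agrees with the exported flux calculator", {
  m <- rat_fixture()$model
  st <- rat_initial_state()
  st[["Ca_ss"]] <- 2e-3   # mid-release conditions exercise the RyR terms
  st[["PO1"]] <- 0.1
  fx <- calcium_fluxes(st, m$params)
  d <- membrane_rhs(0, st[m$state_layout], m)
  names(d) <- m$state_layout
  # JSR balance uses exactly the exported fluxes
  expect_equal(d[["Ca_JSR"]], fx$beta_JSR * (fx$Jtr - fx$Jrel),
               tolerance = 1e-12)
  expect_equal(d[["PO2"]], fx$ryr[["dPO2"]], tolerance = 1e-12)
  expect_equal(d[["HTRPNCa"]], fx$dHTRPNCa, tolerance = 1e-12)
})

test_that("the rat cell is quiescent without a stimulus", {
  m <- rat_fixture()$model
  tr <- simulate_model(m, NULL, solver_options(output_dt = 1),
                       window = c(0, 1000))
  V <- tr$mat[, "V"]
  expect_lt(abs(V[length(V)] - V[length(V) - 1]), 0.05)  # |dV/dt| < 0.05
  expect_lt(max(V), -65)   # no spontaneous firing
})

test_that("the stimulated rat cell fires one action potential with rat morphology", {
  fx <- rat_fixture()
  V <- fx$ref$mat[, "V"]
  t <- fx$ref$t
  expect_gt(max(V), 30)
  expect_lt(max(V), 50)
  # exactly one upstroke crossing of 0 mV
  up <- which(V[-1] > 0 & V[-length(V)] <= 0)
  expect_length(up, 1)
  # resting-to-peak upstroke takes less than 10 ms
  expect_lt(fx$phases[["P1"]] - fx$phases[["P0"]], 10)
})

test_that("all 16 gating variables stay in [0,1] through a 5 s run", {
  fx <- rat_fixture()
  tr <- simulate_model(fx$model, fx$defaults$protocol,
                       solver_options(output_dt = 1))
  for (g in names(fx$model$gates)) {
    x <- tr$mat[, g]
    expect_true(all(x >= -1e-9 & x <= 1 + 1e-9), label = paste("gate", g))
  }
})
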