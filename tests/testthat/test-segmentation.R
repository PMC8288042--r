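test_that("second-derivative sign changes find analytic inflections", {
  t <- seq(0, 2 * pi, by = 0.01)
  cr <- second_derivative_sign_changes(sin(t), dt = 0.01, tol = 1e-4)
  expect_length(cr, 1)
  expect_equal(cr, pi, tolerance = 0.02)
  expect_length(second_derivative_sign_changes(2 + 3 * t, 0.01, tol = 1e-4), 0)
  t2 <- seq(-1, 1, by = 0.002)
  cr2 <- second_derivative_sign_changes(t2^3, dt = 0.002, tol = 1e-4, t0 = -1)
  expect_length(cr2, 1)
  expect_equal(cr2, 0, tolerance = 0.01)
})

test_that("sub-tolerance noise does not move the detected inflections", {
  t <- seq(0, 2 * pi, by = 0.01)
  f <- sin(t)
  set.seed(42)
  noise <- rnorm(length(t), sd = 1e-7)   # curvature noise ~ 1e-7/1e-4 = 1e-3
  tol <- 0.05
  clean <- second_derivative_sign_changes(f, 0.01, tol = tol)
  noisy <- second_derivative_sign_changes(f + noise, 0.01, tol = tol)
  expect_equal(length(clean), length(noisy))
  expect_equal(clean, noisy, tolerance = 0.01)
})

test_that("synthetic waveform phases are recovered at the constructed times", {
  tr <- synthetic_ap()
  truth <- attr(tr, "truth")
  ph <- segment_phases(tr)
  for (p in names(truth))
    expect_lt(abs(ph[[p]] - truth[[p]]), 2 * tr$dt + 1e-9,
              label = paste("phase point", p))
})

test_that("degenerate morphologies are handled explicitly", {
  # no fast early repolarisation: P1-P2 collapses to the grid spacing
  tr0 <- synthetic_ap(plateau_level = 40, d_phase1 = 0.2)
  ph0 <- segment_phases(tr0)
  expect_lt(ph0[["P2"]] - ph0[["P1"]], 3 * tr0$dt)
  # flat trace: explicit failure
  t <- seq(0, 50, by = 0.01)
  flat <- apcontrib:::new_trajectory(t, cbind(V = rep(-80, length(t))),
                                     "flat", NULL,
                                     solver_options(output_dt = 0.01), -80)
  expect_error(segment_phases(flat), "no action potential")
})

test_that("phase overrides replace automatic criteria", {
  tr <- synthetic_ap()
  ph <- segment_phases(tr, overrides = c(P0 = 10.2, P4 = 45))
  expect_equal(ph[["P0"]], 10.2)
  expect_equal(ph[["P4"]], 45)
  expect_error(segment_phases(tr, overrides = c(P9 = 1)), "P9")
  expect_error(segment_phases(tr, overrides = c(P0 = 44, P4 = 43)),
               "increasing")
})

test_that("apd interpolates repolarisation levels and orders fractions", {
  # triangle 0 -> 100 -> 0 over [0.5, 2.5] ms riding on a flat baseline
  t <- seq(0, 4, by = 0.001)
  V <- pmax(0, 100 * (1 - abs(t - 1.5)))
  tri <- apcontrib:::new_trajectory(t, cbind(V = V), "tri", NULL,
                                    solver_options(output_dt = 0.001), 0)
  ph <- segment_phases(tri)
  a50 <- apd(tri, 50, ph)
  # geometry: P0 at the triangle foot, 50% repolarisation 1.5 ms later
  expect_equal(a50 + ph[["P0"]], 2.0, tolerance = 0.01)
  tr <- synthetic_ap()
  ph2 <- segment_phases(tr)
  a <- vapply(c(20, 50, 90), function(f) apd(tr, f, ph2), numeric(1))
  expect_true(all(diff(a) > 0))
  # a trace truncated before repolarising far enough must refuse
  keep <- t <= 2.2
  cut <- apcontrib:::new_trajectory(t[keep], cbind(V = V[keep]), "cut", NULL,
                                    solver_options(output_dt = 0.001), 0)
  ph_cut <- segment_phases(cut)
  expect_error(apd(cut, 90, ph_cut), "never reached")
})

test_that("intervals of interest exactly quarter each phase", {
  tr <- synthetic_ap()
  ph <- segment_phases(tr)
  iois <- make_iois(ph, 4)
  expect_equal(nrow(iois), 16)
  for (p in 0:3) {
    sub <- iois[iois$phase == p, ]
    expect_equal(sub$t_start[1], ph[[p + 1]])
    expect_equal(sub$t_end[4], ph[[p + 2]])
    expect_equal(sub$t_start[-1], sub$t_end[-4])
    expect_equal(diff(range(sub$t_end - sub$t_start)), 0, tolerance = 1e-9)
  }
  one <- make_iois(ph, 1)
  expect_equal(one$t_end - one$t_start, diff(unclass(ph)), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("epochs tile phases without gaps and respect the minimum length", {
  fx <- squid_fixture()
  for (g in c("m", "n")) {
    ep <- build_epochs(fx$ref, g, fx$phases, min_epoch_ms = 0.05)
    expect_true(all(ep$t_end > ep$t_start))
    expect_true(all(ep$t_end - ep$t_start >= 0.05 - 1e-9))
    for (p in 0:3) {
      sub <- ep[ep$phase == p, ]
      expect_equal(sub$t_start[1], fx$phases[[p + 1]])
      expect_equal(sub$t_end[nrow(sub)], fx$phases[[p + 2]])
      if (nrow(sub) > 1)
        expect_equal(sub$t_start[-1], sub$t_end[-nrow(sub)])
      expect_equal(sum(sub$t_end - sub$t_start),
                   fx$phases[[p + 2]] - fx$phases[[p + 1]])
    }
  }
})

test_that("segmentation is stable under grid refinement", {
  tr1 <- synthetic_ap(dt = 0.01)
  tr2 <- synthetic_ap(dt = 0.005)
  ph1 <- segment_phases(tr1)
  ph2 <- segment_phases(tr2)
  expect_true(all(abs(unclass(ph1) - unclass(ph2)) < 2 * 0.01))
})
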