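#' Single-gate threshold model with an exact closed-form event time
#'
#' One gate `x` with voltage-independent steady state and time constant; the
#' membrane potential is a pure readout `V = 100 x` (no feedback), so the
#' time for V to reach the threshold voltage `100 theta` is exactly
#' \eqn{\tau \ln\frac{x_\infty - x_0}{x_\infty - \theta}}.  Because the event
#' time is proportional to \eqn{\tau}, the contribution of `x` to the event
#' duration is exactly 1 for every perturbation fraction — the analytic
#' oracle for the contribution measure.
#'
#' @param tau Gate time constant, ms.
#' @param x_inf Steady-state level (0 < x_inf < 1).
#' @param x0 Initial gate value.
#' @param theta Threshold gate level; requires `x0 < theta < x_inf`.
#' @return A [cell_model()] with attribute `toy`: `theta`, `V_threshold`,
#'   and the analytic `duration`.
#' @export
toy_threshold_model <- function(tau = 2, x_inf = 0.9, x0 = 0,
                                theta = 0.9 * (1 - exp(-1))) {
  if (!(x0 < theta && theta < x_inf && x_inf < 1 && x0 >= 0))
    stop("toy threshold model requires 0 <= x0 < theta < x_inf < 1")
  g <- gate_spec("x", ss = c(0, log(1 / x_inf - 1)),
                 tau = list(c(1 / tau, 0, 0)))
  m <- cell_model("toy-threshold", gates = list(g), channels = list(),
                  capacitance = 1,
                  initial_state = c(V = 100 * x0, x = x0),
                  extra_dynamics = "gate_readout",
                  params = list(readout_gain = 100, readout_gate = "x"))
  attr(m, "toy") <- list(theta = theta, V_threshold = 100 * theta,
                         duration = tau * log((x_inf - x0) / (x_inf - theta)))
  m
}

#' Append a gate that is decoupled from every current
#'
#' The null gate relaxes with its own kinetics but influences nothing, so its
#' measured contribution must vanish in every region — a falsification
#' control for the perturbation machinery.
#'
#' @param model A [cell_model()].
#' @param name Name for the new state variable.
#' @param x_inf,tau Steady-state level and time constant of the null gate.
#' @param x0 Initial value (defaults to 1 - x_inf so the gate visibly
#'   relaxes).
#' @export
add_null_gate <- function(model, name = "znull", x_inf = 0.5, tau = 5,
                          x0 = NULL) {
  if (name %in% model$state_layout) stop("state '", name, "' already exists")
  if (is.null(x0)) x0 <- 1 - x_inf
  g <- gate_spec(name, ss = c(0, log(1 / x_inf - 1)),
                 tau = list(c(1 / tau, 0, 0)))
  out <- cell_model(model$name, gates = c(model$gates, list(g)),
                    channels = model$channels,
                    capacitance = model$capacitance,
                    initial_state = c(model$initial_state,
                                      setNames(x0, name)),
                    constants = model$constants,
                    concentrations = model$concentrations,
                    extra_dynamics = model$extra_dynamics,
                    params = model$params)
  attributes(out)$toy <- attr(model, "toy")
  out
}

# Classic squid-axon kinetics expressed in the declarative gate format.
# The alpha/beta rate constants were converted to (x_inf, tau) and the
# summed rate 1/tau fitted by exponential-basis least squares; the fitted
# time constants agree with the tabulated ones to within 1% for m and n and
# 0.6% for h on [-100, 50] mV, and the denominators stay positive on
# [-120, 80] mV.
.SQUID_GATES <- list(
  m = list(ss = c(-0.104694128145, -4.1432067885),
           tau = list(c(0.122297897875, -0.0555555555556, 0),
                      c(-6.05794087804, -0.02, 0),
                      c(47.6474244982, -0.00714285714286, 0),
                      c(-156.647811541, 0.00571428571429, 0),
                      c(263.553892364, 0.0185714285714, 0),
                      c(-237.572564912, 0.0314285714286, 0),
                      c(123.960942499, 0.0442857142857, 0),
                      c(-34.9427718195, 0.0571428571429, 0),
                      c(4.12048050449, 0.07, 0))),
  h = list(ss = c(0.141466183959, 8.79348817487),
           tau = list(c(13950.6195286, -0.05, 0),
                      c(-116649.376593, -0.045, 0),
                      c(935732.580838, -0.037380952381, 0),
                      c(-5404373.76081, -0.0297619047619, 0),
                      c(22043017.1464, -0.0221428571429, 0),
                      c(-65765975.4552, -0.0145238095238, 0),
                      c(147161307.762, -0.00690476190476, 0),
                      c(-250521381.251, 0.000714285714286, 0),
                      c(326108838.573, 0.00833333333333, 0),
                      c(-323300920.083, 0.0159523809524, 0),
                      c(240391190.056, 0.0235714285714, 0),
                      c(-129622726.588, 0.0311904761905, 0),
                      c(47097287.0136, 0.0388095238095, 0),
                      c(-9366091.22381, 0.0464285714286, 0),
                      c(368499.570448, 0.0616666666667, 0),
                      c(-22734.3397744, 0.0769047619048, 0),
                      c(1036.69745658, 0.0921428571429, 0),
                      c(-6.97120648805, 0.115, 0))),
  n = list(ss = c(-0.0563205653217, -2.87632538524),
           tau = list(c(106.152628673, -0.0125, 0),
                      c(0.831501804401, -0.03, 0),
                      c(-26.3958346288, -0.0185714285714, 0),
                      c(-130.015554875, -0.00714285714286, 0),
                      c(90.6835932731, 0.00428571428571, 0),
                      c(-64.0201085734, 0.0157142857143, 0),
                      c(30.9704859605, 0.0271428571429, 0),
                      c(-8.64217926923, 0.0385714285714, 0),
                      c(1.04325296935, 0.05, 0))))

#' The classic squid-axon membrane model as a generality fixture
#'
#' Four states (V, m, h, n), three currents (fast sodium `m^3 h`, delayed
#' rectifier `n^4`, ohmic leak), membrane capacitance 1, conductances and
#' reversal potentials the standard textbook constants (units muF/cm^2,
#' mS/cm^2, muA/cm^2).  Initial gate values sit at their steady states at
#' the resting potential of -65 mV.
#'
#' @return A [cell_model()].
#' @export
squid_axon_model <- function() {
  gates <- lapply(names(.SQUID_GATES), function(nm)
    gate_spec(nm, ss = .SQUID_GATES[[nm]]$ss, tau = .SQUID_GATES[[nm]]$tau))
  names(gates) <- names(.SQUID_GATES)
  # resting potential of the fitted kinetics: zero net steady-state current
  inet <- function(V) {
    m <- steady_state(gates$m, V); h <- steady_state(gates$h, V)
    n <- steady_state(gates$n, V)
    120 * m^3 * h * (V - 50) + 36 * n^4 * (V + 77) + 0.3 * (V + 54.387)
  }
  v0 <- stats::uniroot(inet, c(-90, -50), tol = 1e-10)$root
  x0 <- vapply(gates, steady_state, numeric(1), V = v0)
  channels <- list(
    channel_spec("Na", g = 120, gates = list(c("m", 3), c("h", 1)),
                 ion = "Na", E_fixed = 50),
    channel_spec("K", g = 36, gates = list(c("n", 4)),
                 ion = "K", E_fixed = -77),
    channel_spec("L", g = 0.3, E_fixed = -54.387))
  cell_model("squid-axon", gates = gates, channels = channels,
             capacitance = 1,
             initial_state = c(V = v0, setNames(x0, names(gates))))
}

#' Synthetic action-potential-like waveform with analytic phase points
#'
#' A deterministic piecewise-cosine waveform (baseline, upstroke, early
#' repolarisation to a plateau, slowly declining plateau, late
#' repolarisation, baseline), C1-continuous, with a single maximum.  The
#' returned trajectory carries a `truth` attribute with the phase-point
#' times implied by the default [phase_criteria()], solved in closed form
#' from the cosine pieces, plus a normalised copy of V as a gate-like
#' column `w` for epoch tests.
#'
#' @param baseline,peak Resting and peak potential, mV.
#' @param plateau_level Potential at the early-repolarisation/plateau
#'   junction, mV; `notch_depth = peak - plateau_level`.
#' @param plateau_drop Slow decline across the plateau, mV (keep its maximum
#'   slope below the plateau-exit threshold).
#' @param t_up Upstroke onset, ms.
#' @param d_up,d_phase1,d_plateau,d_repol Segment durations, ms.
#' @param total Total duration, ms.
#' @param dt Grid spacing, ms.
#' @param noise_sd Optional Gaussian noise amplitude, mV (with `seed`).
#' @param seed RNG seed used only if `noise_sd > 0`.
#' @export
synthetic_ap <- function(baseline = -80, peak = 40, plateau_level = 5,
                         plateau_drop = 3, t_up = 10, d_up = 2,
                         d_phase1 = 4, d_plateau = 12, d_repol = 15,
                         total = 60, dt = 0.01, noise_sd = 0, seed = 1) {
  stopifnot(peak > baseline, plateau_level <= peak, plateau_drop >= 0)
  knots <- cumsum(c(t_up, d_up, d_phase1, d_plateau, d_repol))
  t <- seq(0, total, by = dt)
  ease <- function(s) (1 - cos(pi * pmin(pmax(s, 0), 1))) / 2
  seg <- function(t, a, b, lo, hi) lo + (hi - lo) * ease((t - a) / (b - a))
  V <- rep(baseline, length(t))
  p_end <- plateau_level - plateau_drop
  in1 <- t >= knots[1] & t < knots[2]
  in2 <- t >= knots[2] & t < knots[3]
  in3 <- t >= knots[3] & t < knots[4]
  in4 <- t >= knots[4] & t < knots[5]
  V[in1] <- seg(t[in1], knots[1], knots[2], baseline, peak)
  V[in2] <- seg(t[in2], knots[2], knots[3], peak, plateau_level)
  V[in3] <- seg(t[in3], knots[3], knots[4], plateau_level, p_end)
  V[in4] <- seg(t[in4], knots[4], knots[5], p_end, baseline)
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    V <- V + rnorm(length(V), sd = noise_sd)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  w <- (V - baseline) / (peak - baseline)
  mat <- cbind(V = V, w = w)
  traj <- new_trajectory(t, mat, "synthetic-ap", protocol = NULL,
                         options = solver_options(output_dt = dt),
                         baseline = baseline)
  # closed-form phase points under the default criteria
  crit <- phase_criteria()
  amp_up <- peak - baseline
  # P0: cosine upstroke slope rises through the threshold
  s0 <- asin(min(1, 2 * d_up * crit$upstroke_slope / (amp_up * pi))) / pi
  # P2: early-repolarisation slope comes back above the threshold
  amp1 <- peak - plateau_level
  truth <- c(P0 = knots[1] + s0 * d_up, P1 = knots[2])
  slope1_max <- amp1 * pi / (2 * d_phase1)
  truth["P2"] <- if (slope1_max > abs(crit$phase1_end_slope))
    knots[2] + (1 - asin(2 * d_phase1 * abs(crit$phase1_end_slope) /
                           (amp1 * pi)) / pi) * d_phase1
  else knots[2]
  amp4 <- p_end - baseline
  s3 <- asin(min(1, 2 * d_repol * abs(crit$plateau_exit_slope) / (amp4 * pi))) / pi
  truth["P3"] <- knots[4] + s3 * d_repol
  s4 <- acos(1 - 2 * (amp4 - crit$return_band) / amp4) / pi
  truth["P4"] <- knots[4] + s4 * d_repol
  attr(traj, "truth") <- truth
  attr(traj, "knots") <- knots
  traj
}
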