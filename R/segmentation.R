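# Central finite differences on a uniform grid (same length as the input;
# one-sided at the ends).  `stride` widens the stencil, which divides
# floating-point noise in the second derivative by stride^2 on near-flat
# segments.
finite_diff <- function(y, dt, order = 1L, stride = 1L) {
  n <- length(y)
  m <- stride
  d <- numeric(n)
  i <- (m + 1L):(n - m)
  if (order == 1L) {
    d[i] <- (y[i + m] - y[i - m]) / (2 * m * dt)
    d[1:m] <- d[m + 1L]
    d[(n - m + 1L):n] <- d[n - m]
  } else {
    d[i] <- (y[i + m] - 2 * y[i] + y[i - m]) / (m * dt)^2
    d[1:m] <- d[m + 1L]
    d[(n - m + 1L):n] <- d[n - m]
  }
  d
}

# Times where `series` crosses zero with excursions beyond `tol` on both
# sides; small wiggles that never leave the [-tol, tol] band are ignored.
robust_zero_crossings <- function(series, t, tol) {
  sig <- which(abs(series) > tol)
  if (length(sig) < 2L) return(numeric(0))
  sgn <- sign(series[sig])
  flips <- which(diff(sgn) != 0)
  out <- numeric(0)
  for (k in flips) {
    i1 <- sig[k]; i2 <- sig[k + 1L]
    j <- i1
    while (j < i2 && series[j] * series[j + 1L] > 0) j <- j + 1L
    if (j < i2 || series[i2] == 0) {
      y1 <- series[j]; y2 <- series[j + 1L]
      out <- c(out, t[j] + (t[j + 1L] - t[j]) * y1 / (y1 - y2))
    }
  }
  out
}

#' Zero crossings of the second derivative of a uniform series
#'
#' Central-difference second derivative with a tolerance band: a crossing is
#' reported only where the curvature leaves the `+/- tol` band on both sides
#' of the sign change (robust against floating-point wiggle on flat
#' segments).  Crossing times are linearly interpolated.
#'
#' @param series Numeric series on a uniform grid (length >= 5).
#' @param dt Grid spacing, ms.
#' @param tol Curvature tolerance, series-units/ms^2.
#' @param t0 Time of the first sample, ms.
#' @param stride Stencil half-width in samples (> 1 averages out grid noise
#'   on nearly flat regions).
#' @return Times of the curvature sign changes, ms.
#' @export
second_derivative_sign_changes <- function(series, dt, tol, t0 = 0,
                                           stride = 1L) {
  stopifnot(length(series) >= 5L, dt > 0)
  d2 <- finite_diff(series, dt, order = 2L, stride = stride)
  t <- t0 + (seq_along(series) - 1L) * dt
  robust_zero_crossings(d2, t, tol)
}

#' Phase-detection criteria
#'
#' Thresholds for the automatic placement of the phase points P0-P4.  All
#' are overridable; `overrides` in [segment_phases()] can also pin any point
#' to an explicit time.
#'
#' @param upstroke_slope dV/dt level (mV/ms) whose last upward crossing
#'   before the peak marks P0 (depolarisation onset).
#' @param phase1_end_slope dV/dt level (mV/ms) whose first upward recrossing
#'   after the peak marks P2 (end of rapid early repolarisation / plateau
#'   onset).
#' @param plateau_exit_slope dV/dt level (mV/ms) below which the potential
#'   must fall, sustained, to mark P3 (plateau end).
#' @param sustain_ms How long a slope criterion must hold to count, ms.
#' @param return_band How close (mV) V must get back to the pre-stimulus
#'   baseline to mark P4; if never reached (e.g. sustained current), the
#'   99%-repolarisation time is used, then the settling time.
#' @param min_amplitude Minimum peak height above baseline for the trace to
#'   count as containing an action potential, mV.
#' @export
phase_criteria <- function(upstroke_slope = 1, phase1_end_slope = -1,
                           plateau_exit_slope = -0.5, sustain_ms = 0.5,
                           return_band = 2, min_amplitude = 40) {
  list(upstroke_slope = upstroke_slope, phase1_end_slope = phase1_end_slope,
       plateau_exit_slope = plateau_exit_slope, sustain_ms = sustain_ms,
       return_band = return_band, min_amplitude = min_amplitude)
}

#' Segment an action potential into phases P0-P4
#'
#' P0: last time before the peak at which dV/dt rises through the upstroke
#' threshold.  P1: time of the voltage maximum.  P2: first time after P1 at
#' which dV/dt rises back above the phase-1-end threshold (plateau onset).
#' P3: first later time at which dV/dt falls below the plateau-exit threshold
#' for a sustained interval.  P4: return of V to within `return_band` of the
#' pre-stimulus baseline (with 99%-repolarisation and settling fallbacks for
#' sustained-current protocols).
#'
#' @param traj A trajectory containing exactly one action potential.
#' @param criteria A [phase_criteria()] list.
#' @param overrides Optional named numeric vector pinning any of
#'   `P0 ... P4` to explicit times (ms).
#' @return A `phase_points` object: named times `P0..P4` plus `baseline` and
#'   `peak` attributes.
#' @export
segment_phases <- function(traj, criteria = phase_criteria(),
                           overrides = NULL) {
  V <- traj$mat[, "V"]
  t <- traj$t
  dt <- traj$dt
  base <- traj$baseline
  i_peak <- which.max(V)
  peak <- V[i_peak]
  if (peak < base + criteria$min_amplitude)
    stop("no action potential found: peak ", round(peak, 2),
         " mV is less than ", criteria$min_amplitude,
         " mV above the baseline of ", round(base, 2), " mV")
  dV <- finite_diff(V, dt, order = 1L)
  P1 <- t[i_peak]
  # P0: last upward crossing of the upstroke-slope threshold before the peak.
  # The threshold rides on the baseline drift (median dV/dt over the approach
  # window before the maximal upstroke velocity), so a stimulus-driven
  # subthreshold ramp does not mask the take-off.
  i_dvmax <- which.max(dV[seq_len(i_peak)])
  wlo <- max(1L, i_dvmax - round(8 / dt))
  whi <- max(1L, i_dvmax - round(2 / dt))
  drift <- if (whi > wlo) stats::median(dV[wlo:whi]) else 0
  thr <- criteria$upstroke_slope + max(0, drift)
  pre <- seq_len(i_peak - 1L)
  ups <- pre[dV[pre] < thr & dV[pre + 1L] >= thr]
  if (!length(ups))
    stop("no action potential found: dV/dt never rises through ",
         thr, " mV/ms before the peak")
  j <- ups[length(ups)]
  P0 <- t[j] + dt * (thr - dV[j]) / (dV[j + 1L] - dV[j])
  # P2: dV/dt recrosses the phase-1-end threshold from below.  The rapid
  # early-repolarisation segment must begin at the peak: if dV/dt does not
  # drop through the threshold within a short gap after P1, there is no
  # distinct phase 1 and P2 collapses onto P1.
  thr2 <- criteria$phase1_end_slope
  after <- i_peak:(length(V) - 1L)
  below <- after[dV[after] < thr2]
  P2 <- NA_real_
  if (length(below) && t[below[1]] - P1 <= 2) {
    cand <- after[after > below[1] & dV[after] < thr2 & dV[after + 1L] >= thr2]
    if (length(cand)) {
      j <- cand[1]
      P2 <- t[j] + dt * (thr2 - dV[j]) / (dV[j + 1L] - dV[j])
    }
  }
  if (is.na(P2)) P2 <- P1 + dt  # degenerate: no distinct early repolarisation
  # P3: dV/dt falls below the plateau-exit threshold, sustained
  thr3 <- criteria$plateau_exit_slope
  need <- max(1L, round(criteria$sustain_ms / dt))
  i2 <- which(t >= P2)[1]
  P3 <- NA_real_
  idx <- i2:(length(V) - 1L)
  cross <- idx[dV[idx] >= thr3 & dV[idx + 1L] < thr3]
  for (j in cross) {
    hi <- min(length(V), j + need)
    if (all(dV[(j + 1L):hi] < thr3)) {
      P3 <- t[j] + dt * (thr3 - dV[j]) / (dV[j + 1L] - dV[j])
      break
    }
  }
  if (is.na(P3)) P3 <- P2 + dt
  # P4: return towards baseline
  i3 <- which(t >= P3)[1]
  post <- i3:length(V)
  hit <- post[V[post] <= base + criteria$return_band]
  if (length(hit)) {
    j <- hit[1]
    P4 <- if (j > 1 && V[j - 1L] > base + criteria$return_band) {
      lvl <- base + criteria$return_band
      t[j - 1L] + dt * (V[j - 1L] - lvl) / (V[j - 1L] - V[j])
    } else t[j]
  } else {
    lvl99 <- peak - 0.99 * (peak - base)
    hit99 <- post[V[post] <= lvl99]
    if (length(hit99)) {
      j <- hit99[1]
      P4 <- t[j - 1L] + dt * (V[j - 1L] - lvl99) / (V[j - 1L] - V[j])
    } else {
      settled <- post[post < length(V) - need][
        vapply(post[post < length(V) - need],
               function(j) all(abs(dV[j:(j + need)]) < 0.05), logical(1))]
      P4 <- if (length(settled)) t[settled[1]] else t[length(t)]
    }
  }
  pts <- c(P0 = P0, P1 = P1, P2 = P2, P3 = P3, P4 = P4)
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), names(pts))
    if (length(bad)) stop("unknown phase override(s): ", paste(bad, collapse = ", "))
    pts[names(overrides)] <- overrides
  }
  if (any(diff(pts) <= 0))
    stop("phase points are not strictly increasing: ",
         paste(sprintf("%s=%.3f", names(pts), pts), collapse = ", "))
  structure(pts, baseline = base, peak = peak, class = "phase_points")
}

#' @export
print.phase_points <- function(x, ...) {
  cat("<phase_points> ", paste(sprintf("%s = %.3f ms", names(x), unclass(x)),
                               collapse = ", "), "\n", sep = "")
  cat("  baseline ", round(attr(x, "baseline"), 2), " mV, peak ",
      round(attr(x, "peak"), 2), " mV\n", sep = "")
  invisible(x)
}

#' Build the epoch set of one gating variable
#'
#' Epoch breakpoints are the phase points, the inflection points (curvature
#' sign changes) of the voltage trace, the inflection points of the gate's
#' trajectory, and the local extrema of V (so V is monotone within each
#' epoch, which makes the perturbed-duration stopping rule well posed).
#' Epochs shorter than `min_epoch_ms` are merged into their shorter
#' neighbour.  The returned epochs tile each phase exactly.
#'
#' @param traj A trajectory.
#' @param gate Gate (state) name.
#' @param phases A [segment_phases()] result.
#' @param min_epoch_ms Minimum epoch duration, ms.
#' @param tol_V Curvature tolerance for the voltage trace, mV/ms^2 per mV of
#'   trace amplitude.
#' @param tol_gate Curvature tolerance for the gate trace, 1/ms^2 per unit of
#'   gate amplitude.
#' @param stride Finite-difference stencil half-width (samples).
#' @return A data.frame with one row per epoch: `gate`, `k` (epoch index
#'   across the whole AP), `phase` (0-3), `t_start`, `t_end`, `V_start`,
#'   `V_end`, `increasing` (direction of V).
#' @export
build_epochs <- function(traj, gate, phases, min_epoch_ms = 0.05,
                         tol_V = 2e-4, tol_gate = 2e-4, stride = NULL) {
  t <- traj$t
  dt <- traj$dt
  sel <- t >= phases[["P0"]] & t <= phases[["P4"]]
  tt <- t[sel]
  V <- traj$mat[sel, "V"]
  x <- traj_state(traj, gate)[sel]
  if (is.null(stride)) stride <- max(1L, round(0.02 / dt))
  ampV <- diff(range(V))
  ampx <- max(diff(range(x)), 1e-12)
  infl_V <- second_derivative_sign_changes(V, dt, tol = tol_V * ampV,
                                           t0 = tt[1], stride = stride)
  infl_x <- second_derivative_sign_changes(x, dt, tol = tol_gate * ampx,
                                           t0 = tt[1], stride = stride)
  dV <- finite_diff(V, dt, order = 1L, stride = stride)
  extrema_V <- robust_zero_crossings(dV, tt, tol = 1e-3 * ampV)
  brk <- sort(c(unclass(phases), infl_V, infl_x, extrema_V))
  brk <- brk[brk >= phases[["P0"]] & brk <= phases[["P4"]]]
  brk <- brk[!duplicated(round(brk / dt))]
  rows <- list()
  k <- 0L
  for (p in 0:3) {
    lo <- phases[[p + 1L]]; hi <- phases[[p + 2L]]
    inner <- brk[brk > lo + dt / 2 & brk < hi - dt / 2]
    edges <- c(lo, inner, hi)
    # merge short epochs into the shorter neighbour
    repeat {
      dur <- diff(edges)
      if (length(dur) == 1L || all(dur >= min_epoch_ms)) break
      i <- which.min(dur)
      drop <- if (i == 1L) 2L
        else if (i == length(dur)) i
        else if (dur[i - 1L] <= dur[i + 1L]) i else i + 1L
      edges <- edges[-drop]
    }
    for (e in seq_len(length(edges) - 1L)) {
      k <- k + 1L
      Vs <- approx(tt, V, xout = edges[e])$y
      Ve <- approx(tt, V, xout = edges[e + 1L])$y
      rows[[k]] <- data.frame(gate = gate, k = k, phase = p,
                              t_start = edges[e], t_end = edges[e + 1L],
                              V_start = Vs, V_end = Ve,
                              increasing = Ve >= Vs)
    }
  }
  do.call(rbind, rows)
}

#' Action-potential duration at a repolarisation fraction
#'
#' Duration from P0 to the first post-peak time at which V has repolarised
#' by `fraction` percent of the peak-to-baseline amplitude (linear
#' interpolation between samples).
#'
#' @param traj A trajectory.
#' @param fraction Repolarisation percentage in (0, 100), e.g. 90 for APD90.
#' @param phases Optional precomputed [segment_phases()]; computed if absent.
#' @return Duration in ms.
#' @export
apd <- function(traj, fraction, phases = NULL) {
  stopifnot(fraction > 0, fraction < 100)
  if (is.null(phases)) phases <- segment_phases(traj)
  base <- attr(phases, "baseline")
  peak <- attr(phases, "peak")
  lvl <- peak - fraction / 100 * (peak - base)
  t <- traj$t
  V <- traj$mat[, "V"]
  i_peak <- which(t >= phases[["P1"]])[1]
  post <- i_peak:length(V)
  hit <- post[V[post] <= lvl]
  if (!length(hit))
    stop("repolarisation level for APD", fraction, " (", round(lvl, 2),
         " mV) never reached")
  j <- hit[1]
  tc <- if (j > i_peak) t[j - 1L] + (t[j] - t[j - 1L]) *
    (V[j - 1L] - lvl) / (V[j - 1L] - V[j]) else t[j]
  tc - phases[["P0"]]
}

#' Split each phase into equal intervals of interest
#'
#' @param phases A [segment_phases()] result.
#' @param n Number of equal sub-intervals per phase (default 4).
#' @return Data.frame with `phase`, `label` (`P0IoI1` ...), `t_start`, `t_end`.
#' @export
make_iois <- function(phases, n = 4) {
  stopifnot(n >= 1)
  out <- list()
  for (p in 0:3) {
    lo <- phases[[p + 1L]]; hi <- phases[[p + 2L]]
    edges <- seq(lo, hi, length.out = n + 1L)
    out[[p + 1L]] <- data.frame(
      phase = p, label = paste0("P", p, "IoI", seq_len(n)),
      t_start = edges[-(n + 1L)], t_end = edges[-1L])
  }
  do.call(rbind, out)
}
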