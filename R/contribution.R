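#' Duration of a region after perturbing one gate's time constant
#'
#' Restarts the model from the reference state at the interval start with the
#' gate's time constant scaled by `(1 + delta)` for the whole run, and stops
#' when V crosses the reference end voltage.  The reference duration is
#' `t_end - t_start`; epochs are constructed so that V is monotone over the
#' interval, which makes the stopping level well defined.
#'
#' @param model A [cell_model()].
#' @param ref Reference trajectory (from [simulate_model()]); supplies the
#'   restart state, the end voltage and the stimulus protocol.
#' @param gate Gate name to perturb.
#' @param interval `c(t_start, t_end)` in ms, within the reference span.
#' @param delta Perturbation fraction; `delta = 0` is the identity
#'   perturbation and returns the reference duration without re-integration.
#' @param options [solver_options()] for the perturbed run.
#' @param horizon_factor Give up (with an error) if no crossing occurs within
#'   `horizon_factor` times the reference duration.
#' @return Perturbed duration, ms.
#' @export
perturbed_duration <- function(model, ref, gate, interval, delta,
                               options = solver_options(),
                               horizon_factor = 50) {
  stopifnot(length(interval) == 2L, interval[2] > interval[1])
  if (interval[1] < ref$t[1] - 1e-9 || interval[2] > ref$t[length(ref$t)] + 1e-9)
    stop("interval [", interval[1], ", ", interval[2],
         "] lies outside the reference trajectory span")
  if (!gate %in% names(model$gates)) stop("unknown gate '", gate, "'")
  D <- interval[2] - interval[1]
  if (delta == 0) return(D)
  if (1 + delta <= 0) stop("1 + delta must be positive")
  measure_stop_time(model, ref, gate, interval, delta, options,
                    horizon_factor) - interval[1]
}

# Stop time of a (possibly perturbed) re-integration over one interval:
# first crossing of the reference end voltage, falling back to the run's
# own voltage extremum when the interval ends at a reference extremum that
# the run undershoots.
measure_stop_time <- function(model, ref, gate, interval, delta, options,
                              horizon_factor = 50) {
  D <- interval[2] - interval[1]
  y0 <- state_at(ref, interval[1])
  V_target <- state_at(ref, interval[2])[["V"]]
  at_extremum <- ends_at_extremum(ref, interval[2])
  scl <- if (delta == 0) NULL else setNames(1 + delta, gate)
  horizon <- max(horizon_factor * D, 20 * ref$dt)
  tcross <- integrate_to_crossing(
    model, y0, t0 = interval[1], V_target = V_target,
    horizon = if (at_extremum) max(3 * D, 20 * ref$dt) else horizon,
    protocol = ref$protocol, options = options,
    tau_scale = scl, event = "voltage")
  if (is.na(tcross) && at_extremum) {
    # the run undershoots the reference extremum; the corresponding event
    # is its own extremum (dV/dt root)
    tcross <- integrate_to_crossing(
      model, y0, t0 = interval[1], V_target = V_target, horizon = horizon,
      protocol = ref$protocol, options = options,
      tau_scale = scl, event = "extremum")
  }
  if (is.na(tcross))
    stop("unbounded perturbation effect: gate '", gate, "' on [",
         signif(interval[1], 6), ", ", signif(interval[2], 6),
         "] ms never recrosses the reference end voltage within ",
         horizon_factor, "x the reference duration")
  tcross
}

ends_at_extremum <- function(ref, t_end) {
  i_end <- which.min(abs(ref$t - t_end))
  kk <- max(1L, round(0.2 / ref$dt))
  V <- ref$mat[, "V"]
  if (i_end <= kk || i_end + kk > length(V)) return(FALSE)
  s_before <- V[i_end] - V[i_end - kk]
  s_after <- V[i_end + kk] - V[i_end]
  sign(s_before) != sign(s_after) && s_before != 0
}

#' Contribution of one gate over one interval
#'
#' The contribution is the elasticity of the interval duration with respect
#' to the gate's time constant,
#' \eqn{C = \frac{(D' - D)/D}{\delta}}: positive C means slowing the gate
#' lengthens the region.
#'
#' @inheritParams perturbed_duration
#' @details For an interval ending at a reference voltage extremum the
#'   reference duration is itself re-measured with an unperturbed run using
#'   the identical stopping procedure, so that the discrete-grid offset
#'   between the sampled and the true extremum cancels out of `C` (a gate
#'   with no influence then measures exactly zero).
#' @return A one-row data.frame: `gate`, `t_start`, `t_end`, `D` (reference
#'   duration), `D_perturbed`, `delta`, `C`.
#' @export
contribution_interval <- function(model, ref, gate, interval, delta,
                                  options = solver_options(), ...) {
  D <- interval[2] - interval[1]
  Dp <- perturbed_duration(model, ref, gate, interval, delta, options, ...)
  if (delta != 0 && ends_at_extremum(ref, interval[2]))
    D <- measure_stop_time(model, ref, gate, interval, 0, options, ...) -
      interval[1]
  data.frame(gate = gate, t_start = interval[1], t_end = interval[2],
             D = D, D_perturbed = Dp, delta = delta,
             C = ((Dp - D) / D) / delta)
}

#' Epoch-level contributions of one gate
#'
#' Applies [contribution_interval()] to every epoch row, restarting each
#' perturbed run from the reference state at the epoch start (epochs are
#' treated independently).
#'
#' @inheritParams perturbed_duration
#' @param epochs Epoch table from [build_epochs()].
#' @export
contribution_epochs <- function(model, ref, epochs, delta,
                                options = solver_options()) {
  out <- lapply(seq_len(nrow(epochs)), function(i) {
    r <- contribution_interval(model, ref, epochs$gate[i],
                               c(epochs$t_start[i], epochs$t_end[i]),
                               delta, options)
    r$k <- epochs$k[i]
    r$phase <- epochs$phase[i]
    r
  })
  do.call(rbind, out)
}

check_results <- function(results) {
  if (is.null(results) || nrow(results) == 0L)
    stop("no epoch-level results to aggregate")
  if (length(unique(results$gate)) != 1L || length(unique(results$delta)) != 1L)
    stop("aggregation requires results that share one gate and one delta")
  invisible(results)
}

#' Summed aggregation of epoch contributions
#'
#' The phase-level rule: the sum of the per-epoch normalised contributions,
#' \eqn{C = \sum_k \frac{(D'_k - D_k)/D_k}{\delta}}.
#'
#' @param results Epoch-level results from [contribution_epochs()].
#' @export
aggregate_summed <- function(results) {
  check_results(results)
  sum(results$C)
}

#' Duration-pooled aggregation of epoch contributions
#'
#' The interval-of-interest rule: the fractional change in the *total*
#' duration, \eqn{C = \frac{\sum_k (D'_k - D_k)}{\sum_k D_k} / \delta}
#' (a duration-weighted mean of the per-epoch contributions).
#'
#' @inheritParams aggregate_summed
#' @export
aggregate_pooled <- function(results) {
  check_results(results)
  (sum(results$D_perturbed - results$D) / sum(results$D)) / results$delta[1]
}

#' Expected sign of a contribution
#'
#' The sign rule: if the gating curve moves in the same direction as the
#' membrane potential and the channel's Nernst potential is positive, the
#' contribution is positive; opposite directions give a negative
#' contribution; both signs flip for a negative Nernst potential (potassium).
#'
#' @param ion Ion species (informational).
#' @param gate_direction `"rising"` or `"falling"` over the region.
#' @param V_direction `"depolarizing"` or `"repolarizing"`.
#' @param E_sign `"positive"` or `"negative"` Nernst potential.
#' @return `"+"` or `"-"`.
#' @export
expected_sign <- function(ion, gate_direction = c("rising", "falling"),
                          V_direction = c("depolarizing", "repolarizing"),
                          E_sign = c("positive", "negative")) {
  gate_direction <- match.arg(gate_direction)
  V_direction <- match.arg(V_direction)
  E_sign <- match.arg(E_sign)
  same <- (gate_direction == "rising") == (V_direction == "depolarizing")
  pos <- same == (E_sign == "positive")
  if (pos) "+" else "-"
}

#' Analysis configuration for [run_full_analysis()]
#'
#' @param delta Time-constant perturbation fraction (default 0.10).
#' @param options Solver options for the reference and perturbed runs.
#' @param window Dense-analysis window `c(start, end)` in ms; defaults to a
#'   span around the stimulus onset wide enough to cover one AP.
#' @param gates Gate names to analyse (default: all gates of the model).
#' @param n_ioi Number of equal intervals of interest per phase.
#' @param min_epoch_ms Minimum epoch duration before merging.
#' @param criteria [phase_criteria()] for the automatic phase detection.
#' @param overrides Optional explicit phase times.
#' @param apd_fractions Repolarisation percentages for the APD regions.
#' @param tol_V,tol_gate Curvature tolerances for epoch detection.
#' @export
analysis_config <- function(delta = 0.1, options = solver_options(),
                            window = NULL, gates = NULL, n_ioi = 4,
                            min_epoch_ms = 0.05,
                            criteria = phase_criteria(), overrides = NULL,
                            apd_fractions = c(20, 50, 90),
                            tol_V = 2e-4, tol_gate = 2e-4) {
  list(delta = delta, options = options, window = window, gates = gates,
       n_ioi = n_ioi, min_epoch_ms = min_epoch_ms, criteria = criteria,
       overrides = overrides, apd_fractions = apd_fractions,
       tol_V = tol_V, tol_gate = tol_gate)
}

#' Full regional contribution analysis of a model
#'
#' Simulates the reference trajectory, segments it into phases, builds each
#' gate's epoch set, measures every epoch-level contribution, and aggregates:
#' phases use the summed rule ([aggregate_summed()]); intervals of interest
#' and APD regions use the duration-pooled rule ([aggregate_pooled()]).
#' Expected-sign diagnostics are attached per gate and phase.
#'
#' @param model A [cell_model()].
#' @param protocol A [stimulus_protocol()].
#' @param config An [analysis_config()].
#' @param ref Optional precomputed reference trajectory (skips the reference
#'   simulation).
#' @return A `contribution_table`: data.frame with one row per analysed gate
#'   and one column per region (`P0..P3`, `P0IoI1..`, `AP20/AP50/AP90`),
#'   with attributes `epochs` (per-gate epoch-level results), `phases`,
#'   `iois`, `apd`, `diagnostics` and `errors`.
#' @export
run_full_analysis <- function(model, protocol = stimulus_protocol(),
                              config = analysis_config(), ref = NULL) {
  if (is.null(ref)) {
    window <- config$window
    if (is.null(window))
      window <- c(max(0, protocol$onset - 20),
                  min(protocol$total_time, protocol$onset + 150))
    ref <- simulate_model(model, protocol, config$options, window = window)
  }
  phases <- segment_phases(ref, config$criteria, config$overrides)
  iois <- make_iois(phases, config$n_ioi)
  apd_marks <- setNames(
    vapply(config$apd_fractions, function(f) apd(ref, f, phases), numeric(1)),
    paste0("AP", config$apd_fractions))
  gates <- config$gates
  if (is.null(gates)) gates <- names(model$gates)
  region_labels <- c(paste0("P", 0:3), iois$label, names(apd_marks))
  tab <- as.data.frame(matrix(NA_real_, length(gates), length(region_labels),
                              dimnames = list(gates, region_labels)))
  epoch_store <- list()
  errors <- list()
  for (g in gates) {
    res <- tryCatch({
      ep <- build_epochs(ref, g, phases, config$min_epoch_ms,
                         tol_V = config$tol_V, tol_gate = config$tol_gate)
      contribution_epochs(model, ref, ep, config$delta, config$options)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[g]] <- conditionMessage(res)
      next
    }
    epoch_store[[g]] <- res
    for (p in 0:3) {
      rp <- res[res$phase == p, , drop = FALSE]
      if (nrow(rp)) tab[g, paste0("P", p)] <- aggregate_summed(rp)
    }
    # IoIs and APD regions pool the epochs lying under them; epochs
    # straddling a region boundary are cut there, and each cut segment is
    # measured by its own perturbation run (segments inherit epoch
    # monotonicity, so the stopping rule stays well posed)
    cuts <- sort(unique(c(iois$t_start, iois$t_end,
                          phases[["P0"]] + unname(apd_marks))))
    seg <- tryCatch(
      refine_and_measure(model, ref, ep, cuts, config$delta, config$options),
      error = function(e) e)
    if (inherits(seg, "error")) {
      errors[[g]] <- conditionMessage(seg)
      next
    }
    pool_over <- function(lo, hi) {
      rs <- seg[seg$t_start >= lo - 1e-9 & seg$t_end <= hi + 1e-9, , drop = FALSE]
      if (nrow(rs)) aggregate_pooled(rs) else NA_real_
    }
    for (i in seq_len(nrow(iois)))
      tab[g, iois$label[i]] <- pool_over(iois$t_start[i], iois$t_end[i])
    for (a in names(apd_marks))
      tab[g, a] <- pool_over(phases[["P0"]], phases[["P0"]] + apd_marks[[a]])
  }
  diag <- sign_diagnostics(model, ref, phases, tab, gates)
  structure(tab, epochs = epoch_store, phases = phases, iois = iois,
            apd = apd_marks, delta = config$delta,
            mode = c(phases = "summed", iois = "pooled", apd = "pooled"),
            diagnostics = diag, errors = errors,
            class = c("contribution_table", "data.frame"))
}

# Cut the epoch tiling at additional region boundaries and measure every
# resulting segment (skipping slivers below 1e-6 ms).
refine_and_measure <- function(model, ref, epochs, cuts, delta, options) {
  rows <- list()
  for (i in seq_len(nrow(epochs))) {
    lo <- epochs$t_start[i]; hi <- epochs$t_end[i]
    inner <- cuts[cuts > lo + 1e-9 & cuts < hi - 1e-9]
    edges <- c(lo, inner, hi)
    for (e in seq_len(length(edges) - 1L)) {
      if (edges[e + 1L] - edges[e] < 1e-6) next
      r <- contribution_interval(model, ref, epochs$gate[i],
                                 c(edges[e], edges[e + 1L]), delta, options)
      r$k <- epochs$k[i]
      r$phase <- epochs$phase[i]
      rows[[length(rows) + 1L]] <- r
    }
  }
  do.call(rbind, rows)
}

# Per (gate, phase): direction of the gate trace, direction of V, Nernst
# sign of the gate's channel, the sign rule's prediction and the observed
# sign of the phase-level contribution.
sign_diagnostics <- function(model, ref, phases, tab, gates) {
  gate_ion <- gate_ion_map(model)
  rows <- list()
  for (g in gates) {
    ion <- gate_ion[[g]]
    if (is.null(ion)) next
    E <- reversal_at_initial(model, ion)
    for (p in 0:3) {
      lo <- phases[[p + 1L]]; hi <- phases[[p + 2L]]
      x <- traj_state(ref, g)[ref$t >= lo & ref$t <= hi]
      V <- traj_state(ref, "V")[ref$t >= lo & ref$t <= hi]
      gd <- if (x[length(x)] >= x[1]) "rising" else "falling"
      vd <- if (V[length(V)] >= V[1]) "depolarizing" else "repolarizing"
      pred <- expected_sign(ion, gd, vd, if (E > 0) "positive" else "negative")
      obs <- tab[g, paste0("P", p)]
      rows[[length(rows) + 1L]] <- data.frame(
        gate = g, phase = p, ion = ion, E = E, gate_direction = gd,
        V_direction = vd, expected = pred,
        observed = if (is.na(obs)) NA_character_
                   else if (obs >= 0) "+" else "-",
        C = obs)
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

gate_ion_map <- function(model) {
  out <- list()
  for (ch in model$channels)
    for (gp in ch$gates)
      if (is.null(out[[gp$gate]]) && !is.null(ch$ion)) out[[gp$gate]] <- ch$ion
  out
}

reversal_at_initial <- function(model, ion) {
  # the first channel of this species defines its reversal; fixed E wins
  for (ch in model$channels) {
    if (is.null(ch$ion) || ch$ion != ion) next
    if (!is.null(ch$E_fixed)) return(ch$E_fixed)
    ci_name <- paste0(ion, "_i")
    c_in <- if (ci_name %in% model$state_layout)
      model$initial_state[[ci_name]] else model$concentrations[[ci_name]]
    return(nernst(.ION_Z[[ion]], model$concentrations[[paste0(ion, "_o")]],
                  c_in, model$constants))
  }
  0
}

#' @export
print.contribution_table <- function(x, digits = 4, ...) {
  cat("<contribution_table> delta =", attr(x, "delta"), "\n")
  print.data.frame(round(as.data.frame(x), digits))
  err <- attr(x, "errors")
  if (length(err))
    cat("cells with errors:", paste(names(err), collapse = ", "), "\n")
  invisible(x)
}
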