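# Registry of built-in non-gating dynamics blocks (calcium handling, ion
# bookkeeping, pump currents).  A model-spec file references one by name.
.extra_dynamics_registry <- new.env(parent = emptyenv())

#' Register a named non-gating dynamics block
#'
#' The hook is called once per right-hand-side evaluation as
#' `fn(t, state, ctx)` where `ctx` carries `V`, the named gate values and
#' their derivatives, the channel currents and reversal potentials, and the
#' model (with `model$params`).  It returns a list with any of
#' `currents` (named, pA, added to the membrane equation), `deriv` (named
#' derivatives for non-gate state variables) and `dV_add` (additive term on
#' dV/dt, used by readout-style fixtures).
#'
#' @param name Registry key.
#' @param fn Hook function.
#' @export
register_extra_dynamics <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  assign(name, fn, envir = .extra_dynamics_registry)
  invisible(name)
}

get_extra_dynamics <- function(ref) {
  if (is.null(ref) || is.function(ref)) return(ref)
  if (!exists(ref, envir = .extra_dynamics_registry))
    stop("unknown extra_dynamics '", ref, "'")
  get(ref, envir = .extra_dynamics_registry)
}

#' Assemble a Hodgkin-Huxley-type cell model
#'
#' Bundles gating kinetics, channel definitions, membrane capacitance,
#' physical constants, ion concentrations, an ordered initial state and an
#' optional non-gating dynamics hook into a validated, simulatable object.
#' The membrane equation is
#' \eqn{C_m \, dV/dt = -\sum_Y I_Y + I_{app}}, gate rows follow the
#' first-order relaxation law, and remaining state rows delegate to the hook.
#'
#' @param name Model name.
#' @param gates List of [gate_spec()] objects.
#' @param channels List of [channel_spec()] objects.
#' @param capacitance Membrane capacitance, pF.
#' @param initial_state Named numeric vector; its names define the state
#'   layout.  Must contain `"V"` and every gate name exactly once.
#' @param constants A [physical_constants()] list.
#' @param concentrations Named list of fixed concentrations in mM:
#'   extracellular `Na_o`, `K_o`, `Ca_o`, `Cl_o` and, for any ion whose
#'   intracellular concentration is not a state variable (`Na_i` etc.), the
#'   fixed intracellular value.
#' @param extra_dynamics `NULL`, a function, or the name of a registered
#'   dynamics block (see [register_extra_dynamics()]).
#' @param params Parameter list handed to the extra-dynamics hook.
#' @return An object of class `cell_model`.
#' @export
cell_model <- function(name, gates, channels, capacitance, initial_state,
                       constants = physical_constants(),
                       concentrations = list(),
                       extra_dynamics = NULL, params = list()) {
  stopifnot(is.numeric(capacitance), capacitance > 0)
  layout <- names(initial_state)
  if (is.null(layout) || anyDuplicated(layout) || any(!nzchar(layout)))
    stop("initial_state must be a named vector with unique non-empty names")
  if (!"V" %in% layout) stop("state layout must contain 'V'")
  gate_names <- vapply(gates, function(g) g$name, character(1))
  if (anyDuplicated(gate_names)) stop("duplicate gate names")
  missing_gates <- setdiff(gate_names, layout)
  if (length(missing_gates))
    stop("gates not present in the state layout: ",
         paste(missing_gates, collapse = ", "))
  names(gates) <- gate_names
  for (ch in channels) {
    for (gp in ch$gates)
      if (!gp$gate %in% gate_names)
        stop("channel '", ch$name, "' references undefined gate '", gp$gate, "'")
    if (!is.null(ch$ion) && is.null(ch$E_fixed)) {
      if (is.null(concentrations[[paste0(ch$ion, "_o")]]))
        stop("channel '", ch$name, "': extracellular ", ch$ion,
             " concentration missing")
      if (!paste0(ch$ion, "_i") %in% layout &&
          is.null(concentrations[[paste0(ch$ion, "_i")]]))
        stop("channel '", ch$name, "': intracellular ", ch$ion,
             " concentration neither a state variable nor fixed")
    }
  }
  model <- structure(
    list(name = name, gates = gates, channels = channels,
         capacitance = as.numeric(capacitance),
         initial_state = initial_state, state_layout = layout,
         constants = constants, concentrations = concentrations,
         extra_dynamics = extra_dynamics, params = params,
         clamp = FALSE),
    class = "cell_model")
  model$compiled <- compile_model(model)
  validate_cell_model(model)
  model
}

validate_cell_model <- function(model) {
  Vgrid <- seq(-120, 80, by = 2)
  for (g in model$gates) {
    if (!identical(g$driver, "V")) next
    tau <- time_constant(g, Vgrid)
    if (any(tau <= 0) || any(!is.finite(tau)))
      stop("gate '", g$name, "': time constant not strictly positive on [-120, 80] mV")
    xs <- steady_state(g, Vgrid)
    if (any(xs <= 0) || any(xs >= 1))
      stop("gate '", g$name, "': steady state leaves (0, 1) on [-120, 80] mV")
  }
  d <- membrane_rhs(0, model$initial_state, model)
  if (any(!is.finite(d)))
    stop("right-hand side not finite at the initial state (components: ",
         paste(model$state_layout[!is.finite(d)], collapse = ", "), ")")
  invisible(model)
}

# Precompute index structures so the RHS is a handful of vectorised
# operations; called once from cell_model().
compile_model <- function(model) {
  layout <- model$state_layout
  gate_names <- names(model$gates)
  ng <- length(gate_names)
  gi <- match(gate_names, layout)
  driver_idx <- vapply(model$gates, function(g) {
    i <- match(g$driver, layout)
    if (is.na(i)) stop("gate '", g$name, "': driver '", g$driver,
                       "' is not a state variable")
    i
  }, integer(1))
  a1 <- vapply(model$gates, function(g) g$ss[1], numeric(1))
  a2 <- vapply(model$gates, function(g) g$ss[2], numeric(1))
  terms <- do.call(rbind, lapply(seq_along(model$gates), function(k) {
    tt <- do.call(rbind, model$gates[[k]]$tau)
    cbind(tt, k)
  }))
  # gate-by-term selector matrix: denom = tsel %*% per-term rates
  tsel <- matrix(0, ng, nrow(terms))
  tsel[cbind(terms[, 4], seq_len(nrow(terms)))] <- 1
  ion_plan <- lapply(model$channels, function(ch) {
    if (!is.null(ch$E_fixed)) return(list(fixed = ch$E_fixed))
    ci_name <- paste0(ch$ion, "_i")
    list(z = .ION_Z[[ch$ion]],
         c_out = model$concentrations[[paste0(ch$ion, "_o")]],
         c_in_idx = match(ci_name, layout),
         c_in_fixed = model$concentrations[[ci_name]])
  })
  list(layout = layout, nstate = length(layout), v_idx = match("V", layout),
       gate_names = gate_names, ng = ng, gi = gi, driver_idx = driver_idx,
       a1 = a1, a2 = a2,
       tb = terms[, 1], tc = terms[, 2], td = terms[, 3],
       tdrv = driver_idx[terms[, 4]], tsel = tsel,
       g = vapply(model$channels, function(ch) ch$g, numeric(1)),
       ch_names = vapply(model$channels, function(ch) ch$name, character(1)),
       ch_gidx = lapply(model$channels,
                        function(ch) match(vapply(ch$gates, `[[`, character(1), "gate"),
                                           gate_names)),
       ch_pow = lapply(model$channels,
                       function(ch) vapply(ch$gates, `[[`, integer(1), "power")),
       ch_scale = lapply(model$channels, function(ch) ch$scale),
       ion_plan = ion_plan,
       rtf = model$constants$R * model$constants$T / model$constants$F,
       extra = get_extra_dynamics(model$extra_dynamics),
       cache = new.env(parent = emptyenv()))
}

#' Right-hand side of the assembled model ODE system
#'
#' @param t Time, ms.
#' @param state Named (or layout-ordered) numeric state vector.
#' @param model A [cell_model()].
#' @param i_app Applied current at `t`, pA (scalar or a `function(t)`).
#' @param tau_scale Named multiplicative scale on selected gates' time
#'   constants (the perturbation hook); default none.
#' @return Numeric derivative vector in state-layout order.
#' @export
membrane_rhs <- function(t, state, model, i_app = 0, tau_scale = NULL) {
  cm <- model$compiled
  y <- as.numeric(state)
  if (length(y) != cm$nstate) stop("state length does not match the model layout")
  if (is.function(i_app)) i_app <- i_app(t)
  rhs_core(t, y, model, i_app, tau_scale_vector(model, tau_scale))
}

# Expand a named tau_scale into a full per-gate multiplier vector.
tau_scale_vector <- function(model, tau_scale) {
  cm <- model$compiled
  scl <- rep(1, cm$ng)
  if (!is.null(tau_scale)) {
    idx <- match(names(tau_scale), cm$gate_names)
    if (anyNA(idx)) stop("tau_scale names unknown gate(s): ",
                         paste(names(tau_scale)[is.na(idx)], collapse = ", "))
    scl[idx] <- tau_scale
  }
  scl
}

rhs_core <- function(t, y, model, i_app, scl) {
  cm <- model$compiled
  y <- unname(y)
  V <- y[cm$v_idx]
  x <- y[cm$gi]
  u <- y[cm$driver_idx]
  x_inf <- 1 / (1 + exp_clamped(cm$a1 * u + cm$a2))
  denom <- as.numeric(cm$tsel %*% (cm$tb * exp_clamped(cm$tc * y[cm$tdrv] + cm$td)))
  tau <- scl / denom
  dx <- (x_inf - x) / tau
  nch <- length(cm$g)
  I <- numeric(nch)
  E <- numeric(nch)
  for (j in seq_len(nch)) {
    plan <- cm$ion_plan[[j]]
    E[j] <- if (!is.null(plan$fixed)) plan$fixed else {
      c_in <- if (!is.na(plan$c_in_idx)) y[plan$c_in_idx] else plan$c_in_fixed
      cm$rtf / plan$z * log(plan$c_out / c_in)
    }
    open <- prod(x[cm$ch_gidx[[j]]]^cm$ch_pow[[j]])
    if (!is.null(cm$ch_scale[[j]])) open <- open * cm$ch_scale[[j]](V)
    I[j] <- cm$g[j] * open * (V - E[j])
  }
  d <- numeric(cm$nstate)
  d[cm$gi] <- dx
  i_extra <- 0
  if (!is.null(cm$extra)) {
    names(I) <- cm$ch_names
    names(E) <- cm$ch_names
    gv <- x; names(gv) <- cm$gate_names
    dxn <- dx; names(dxn) <- cm$gate_names
    ex <- cm$extra(t, y, list(V = V, gates = gv, dx = dxn, currents = I,
                              E = E, model = model))
    if (!is.null(ex$deriv)) {
      idx <- cm$cache$deriv_idx
      if (is.null(idx)) {
        idx <- match(names(ex$deriv), cm$layout)
        if (anyNA(idx)) stop("extra_dynamics returned derivatives for unknown state(s): ",
                             paste(names(ex$deriv)[is.na(idx)], collapse = ", "))
        cm$cache$deriv_idx <- idx
      }
      d[idx] <- d[idx] + as.numeric(ex$deriv)
    }
    if (!is.null(ex$currents)) i_extra <- sum(ex$currents)
    if (!is.null(ex$dV_add)) d[cm$v_idx] <- d[cm$v_idx] + ex$dV_add
  }
  if (!isTRUE(model$clamp))
    d[cm$v_idx] <- d[cm$v_idx] + (-(sum(I) + i_extra) + i_app) / model$capacitance
  if (any(!is.finite(d)))
    stop("non-finite derivative at t = ", t, " (components: ",
         paste(cm$layout[!is.finite(d)], collapse = ", "), ")")
  d
}

#' Hold the membrane potential fixed (voltage clamp)
#'
#' Returns a copy of the model whose `dV/dt` is forced to zero; optionally
#' resets the clamped potential.  Used for closed-form gate-relaxation checks
#' and steady-state protocols.
#'
#' @param model A [cell_model()].
#' @param V Optional holding potential, mV.
#' @export
clamp_model <- function(model, V = NULL) {
  model$clamp <- TRUE
  if (!is.null(V)) model$initial_state[["V"]] <- V
  model
}

#' @export
print.cell_model <- function(x, ...) {
  cat("<cell_model> ", x$name, "\n", sep = "")
  cat("  states: ", length(x$state_layout),
      " (", paste(head(x$state_layout, 8), collapse = ", "),
      if (length(x$state_layout) > 8) ", ..." else "", ")\n", sep = "")
  cat("  gates:  ", length(x$gates), " | channels: ", length(x$channels),
      " | Cm = ", x$capacitance, " pF\n", sep = "")
  invisible(x)
}
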