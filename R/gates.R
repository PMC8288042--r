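# Exponent clamp: stiff solvers probe extreme voltages during Newton
# iterations; +/-500 keeps exp() finite without affecting any physical range.
.EXP_CLAMP <- 500

# Only the upper clamp matters: exp() underflows harmlessly to zero, but an
# overflow to Inf would poison the solver.
exp_clamped <- function(z) exp(pmin(z, .EXP_CLAMP))

#' Define one gating variable
#'
#' A gate relaxes towards a sigmoid steady state
#' \eqn{x_\infty(V) = 1 / (1 + e^{a_1 V + a_2})} with voltage-dependent time
#' constant \eqn{\tau_x(V) = 1 / \sum_i b_i e^{c_i V + d_i}} (a sum of
#' exponentials in the denominator, so any number of terms shapes the
#' bell/monotone profile).
#'
#' @param name Gate identifier (must match a state-variable name).
#' @param ss Numeric length-2, the steady-state coefficients `c(a1, a2)`;
#'   `a1` in 1/mV, `a2` dimensionless.  `a1 > 0` gives a gate that closes
#'   with depolarisation (inactivation), `a1 < 0` one that opens (activation).
#' @param tau List (or n x 3 matrix) of `c(b, c, d)` triples; `b` in 1/ms,
#'   `c` in 1/mV, `d` dimensionless.  At least one term, all `b >= 0` with at
#'   least one `b > 0`.
#' @param driver Name of the state variable the sigmoid and time constant are
#'   evaluated at.  Default `"V"`; a calcium-dependent inactivation gate uses
#'   the subspace calcium concentration instead.
#' @return An object of class `gate_spec`.
#' @examples
#' g <- gate_spec("n", ss = c(-0.18, -7.6), tau = list(c(4, 0.03, 0), c(4, -0.05, -2)))
#' steady_state(g, -40)
#' time_constant(g, -40)
#' @export
gate_spec <- function(name, ss, tau, driver = "V") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  ss <- as.numeric(ss)
  if (length(ss) != 2L || any(!is.finite(ss)))
    stop("gate '", name, "': ss must be two finite numbers c(a1, a2)")
  if (is.matrix(tau)) tau <- lapply(seq_len(nrow(tau)), function(i) tau[i, ])
  if (!is.list(tau) || length(tau) == 0L)
    stop("gate '", name, "': tau must be a non-empty list of c(b, c, d) triples")
  tau <- lapply(tau, function(term) {
    term <- as.numeric(term)
    if (length(term) != 3L || any(!is.finite(term)))
      stop("gate '", name, "': each tau term must be a finite triple c(b, c, d)")
    term
  })
  b <- vapply(tau, `[`, numeric(1), 1L)
  if (all(b == 0))
    stop("gate '", name, "': at least one tau rate coefficient must be non-zero")
  out <- structure(list(name = name, ss = ss, tau = tau, driver = driver),
                   class = "gate_spec")
  if (identical(driver, "V")) {
    # invariant: the summed rate must stay positive over the physiological range
    tc <- time_constant(out, seq(-120, 80, by = 1))
    if (any(tc <= 0) || any(!is.finite(tc)))
      stop("gate '", name, "': time constant not strictly positive on [-120, 80] mV")
  }
  out
}

#' Steady-state (asymptotic) open fraction of a gate
#'
#' \eqn{x_\infty(V) = 1 / (1 + e^{a_1 V + a_2})}.  Overflow-safe: saturates to
#' 0 or 1 for extreme arguments, never NaN.
#'
#' @param gate A [gate_spec()].
#' @param V Membrane potential in mV (vectorised).  For a gate with a
#'   non-voltage `driver` this is the driver value in its own units.
#' @return Open fraction in (0, 1).
#' @export
steady_state <- function(gate, V) {
  stopifnot(inherits(gate, "gate_spec"), all(is.finite(V)))
  1 / (1 + exp_clamped(gate$ss[1] * V + gate$ss[2]))
}

#' Relaxation time constant of a gate
#'
#' \eqn{\tau_x(V) = 1 / \sum_i b_i e^{c_i V + d_i}}, in ms; strictly positive.
#'
#' @inheritParams steady_state
#' @return Time constant in ms.
#' @export
time_constant <- function(gate, V) {
  stopifnot(inherits(gate, "gate_spec"), all(is.finite(V)))
  denom <- 0
  for (term in gate$tau)
    denom <- denom + term[1] * exp_clamped(term[2] * V + term[3])
  if (any(denom <= 0))
    stop("time constant denominator underflowed to zero for gate '",
         gate$name, "' at V = ", paste(V[denom <= 0], collapse = ", "), " mV")
  1 / denom
}

#' First-order relaxation rate of a gate
#'
#' \eqn{dx/dt = (x_\infty(V) - x) / \tau_x(V)}; zero exactly at the fixed
#' point \eqn{x = x_\infty(V)}.
#'
#' @param x Current gate value in `[0, 1]`.
#' @inheritParams steady_state
#' @return Rate of change in 1/ms.
#' @export
gate_derivative <- function(x, gate, V) {
  stopifnot(all(x >= 0 & x <= 1))
  (steady_state(gate, V) - x) / time_constant(gate, V)
}

#' Nernst (reversal) potential
#'
#' \eqn{E = (RT / zF)\,\ln(c_{out} / c_{in})} in mV.  `R` is taken in
#' mJ/(mol K) so the result is directly in mV.
#'
#' @param z Ion valence (-1, +1 or +2).
#' @param c_out,c_in Extracellular / intracellular concentration in mM; must
#'   be strictly positive.
#' @param constants A [physical_constants()] list.
#' @return Reversal potential in mV.
#' @examples
#' nernst(1, 5.4, 139.275) # potassium, about -86.9 mV
#' @export
nernst <- function(z, c_out, c_in, constants = physical_constants()) {
  if (any(c_out <= 0) || any(c_in <= 0))
    stop("nernst: concentrations must be strictly positive")
  if (!all(z %in% c(-1, 1, 2))) stop("nernst: valence must be -1, +1 or +2")
  with(constants, (R * T) / (z * F) * log(c_out / c_in))
}

#' Physical constants
#'
#' Faraday constant (C/mol), absolute temperature (K) and ideal gas constant
#' in mJ/(mol K), the unit convention that makes [nernst()] return mV.
#'
#' @param F Faraday constant, C/mol.
#' @param T Absolute temperature, K.
#' @param R Ideal gas constant, mJ/(mol K).
#' @export
physical_constants <- function(F = 96487, T = 310.15, R = 8314) {
  stopifnot(F > 0, T > 0, R > 0)
  list(F = F, T = T, R = R)
}
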