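#' Define one ionic channel
#'
#' A channel current has the product form
#' \eqn{I_Y = \bar g_Y \, a^M b^N c^L (V - E_{ion})}: a maximal conductance, a
#' product of gating variables raised to small integer powers, and an ohmic
#' driving force.  The reversal potential is either fixed or computed from the
#' Nernst equation for the channel's ion using instantaneous intracellular
#' concentrations when those are state variables.
#'
#' @param name Channel identifier (e.g. `"Na"`, `"CaL"`, `"K1"`).
#' @param g Maximal conductance, nS; `>= 0`.
#' @param gates List of `c(gate_name, power)` pairs (power a non-negative
#'   integer); may be empty for an ungated (background) channel.
#' @param ion Ion species: one of `"Na"`, `"K"`, `"Ca"`, `"Cl"`.  Used for
#'   the Nernst reversal potential unless `E_fixed` is given, in which case
#'   it only labels the species (for the sign convention).
#' @param E_fixed Fixed reversal potential in mV; overrides the Nernst
#'   computation.
#' @param rectification Optional `list(Vh, k)` describing an instantaneous
#'   (ungated) sigmoid conductance scale `1/(1 + exp((V - Vh)/k))`, used for
#'   the inward rectification of IK1.  Declarative, so it survives model-file
#'   round trips.
#' @param scale Optional arbitrary conductance scale `function(V)`;
#'   programmatic alternative to `rectification` (not serialisable).
#' @return An object of class `channel_spec`.
#' @export
channel_spec <- function(name, g, gates = list(), ion = NULL, E_fixed = NULL,
                         rectification = NULL, scale = NULL) {
  if (!is.null(rectification)) {
    stopifnot(is.null(scale), !is.null(rectification$Vh), !is.null(rectification$k))
    vh <- rectification$Vh; kk <- rectification$k
    scale <- function(V) 1 / (1 + exp_clamped((V - vh) / kk))
  }
  stopifnot(is.character(name), length(name) == 1L, is.numeric(g), g >= 0)
  if (is.null(ion) && is.null(E_fixed))
    stop("channel '", name, "': give an ion (Nernst reversal) and/or E_fixed")
  if (!is.null(ion) && !ion %in% c("Na", "K", "Ca", "Cl"))
    stop("channel '", name, "': unknown ion '", ion, "'")
  gates <- lapply(gates, function(gp) {
    nm <- as.character(gp[[1]]); p <- as.numeric(gp[[2]])
    if (p < 0 || p != round(p))
      stop("channel '", name, "': gate powers must be non-negative integers")
    list(gate = nm, power = as.integer(p))
  })
  structure(list(name = name, g = as.numeric(g), gates = gates, ion = ion,
                 E_fixed = if (is.null(E_fixed)) NULL else as.numeric(E_fixed),
                 rectification = rectification, scale = scale),
            class = "channel_spec")
}

#' Evaluate one channel current
#'
#' \eqn{I = \bar g \prod_j x_j^{p_j} (V - E)}.  With the conductance in nS and
#' potentials in mV the current is in pA.
#'
#' @param channel A [channel_spec()].
#' @param gate_values Named numeric vector of gate open fractions in `[0, 1]`.
#' @param V Membrane potential, mV.
#' @param E Reversal potential, mV.
#' @return Current in pA (positive = outward).
#' @export
channel_current <- function(channel, gate_values, V, E) {
  stopifnot(inherits(channel, "channel_spec"))
  open <- 1
  for (gp in channel$gates) {
    if (!gp$gate %in% names(gate_values))
      stop("channel '", channel$name, "' references gate '", gp$gate,
           "' which is not among the supplied gate values")
    open <- open * gate_values[[gp$gate]]^gp$power
  }
  if (!is.null(channel$scale)) open <- open * channel$scale(V)
  channel$g * open * (V - E)
}

# Valence lookup used when a channel's reversal potential is Nernst-computed.
.ION_Z <- c(Na = 1, K = 1, Ca = 2, Cl = -1)
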