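# ---------------------------------------------------------------------------
# Bundled adult rat left-ventricular cardiomyocyte model (30 states).
#
# Printed, verbatim parameter sources:
#   * channel maximal conductances          -> params$g            (nS)
#   * Ca2+ handling / physical constants    -> params$ca, constants
#   * initial state                         -> rat_initial_state()
#   * extracellular concentrations          -> concentrations
# Package-authored (synthetic) components, documented in the methods
# vignette: the gating kinetics (slopes and time-constant profiles,
# calibrated so the model reproduces adult rat LV action-potential
# morphology; sigmoid midpoints are pinned so that the tabulated initial
# state is the resting steady state at -72 mV), the pump/exchanger
# magnitudes, the IK1 rectification shape, and the fixed reversal
# potentials of the CaL/CaT/f channels.
# ---------------------------------------------------------------------------

#' Parameter set of the bundled rat left-ventricular model
#'
#' Returns the full nested parameter list: `g` (channel maximal
#' conductances, nS), `ca` (sarcoplasmic-reticulum and buffering
#' parameters), `pumps` (Na+/K+ pump, Na+/Ca2+ exchanger and sarcolemmal
#' Ca2+ pump), `gating` (per-gate slope and time-constant profile),
#' `K1` (inward-rectification shape) and `E_fixed` reversal potentials.
#' Every entry can be overridden through `build_rat_model(overrides=)`.
#'
#' @export
rat_model_parameters <- function() {
  list(
    capacitance = 100,          # pF
    g = c(Na = 1.0044e+3, t0 = 6.4718, f = 7.7282, K1 = 6, Kr = 5.7017,
          CaL = 6.2894, Ks = 6.4916, CaT = 1.5854, Clb = 1.5278,
          BNa = 0.0326, BK = 0.0500, BCa = 0.0025),  # nS
    ca = list(
      v1 = 10.5921,             # RyR release rate, 1/ms
      Kfb = 9.6176e-4, Krb = 28.1467, Ksr = 2.3974, Nfb = 1.2, Nrb = 1,
      vmaxf = 0.00004, vmaxr = 0.0009,   # SERCA limb rates, mM/ms
      tau_tr = 0.9258, tau_xfer = 0.5234, # inter-compartment transfer, ms
      ka_p = 5.78e+6, ka_m = 0.5128,     # RyR PC1<->PO1, mM^-4/ms, 1/ms
      kb_p = 2.1586e+7, kb_m = 3.4472,   # RyR PO1<->PO2, mM^-3/ms, 1/ms
      kc_p = 0.0513, kc_m = 0.0062,      # RyR PO1<->PC2, 1/ms
      khtrpn_p = 43.1286, khtrpn_m = 7.1033e-4,  # troponin high-affinity
      kltrpn_p = 0.0969, kltrpn_m = 0.0013,      # troponin low-affinity
      HTRPNtot = 0.14, LTRPNtot = 0.07,
      CMDNtot = 0.05, KmCMDN = 0.00238,
      CSQNtot = 15, KmCSQN = 0.8,
      EGTAtot = 10, KmEGTA = 0.00015,    # carried; disabled by default
      egta_enabled = FALSE,
      Vmyo = 9.36, VJSR = 0.056, Vss = 0.0012, VNSR = 0.504,  # pL
      Acap = 0.8004),
    pumps = list(
      INaK_max = 60,            # pA
      Km_Nai = 10, Km_Ko = 1.5, # mM
      k_NaCa = 8000,            # pA scale of the exchanger
      Km_Na = 87.5, Km_Ca = 1.38, k_sat = 0.1, eta = 0.35,
      ICaP_max = 8, Km_CaP = 5e-4),
    K1 = list(Vh = -52, k = 6),   # rectification midpoint/steepness, mV
    E_fixed = c(CaL = 65, CaT = 50, f = -20),  # mV
    # per-gate kinetics: slope k (mV), tau profile (peak ms, centre mV,
    # left/right rate 1/mV); sigmoid midpoints derive from the initial state
    # unless Vh is given explicitly
    gating = list(
      n   = list(type = "act",   k = 5.5, tau_max = 0.4,  Vp = -42, cl = 0.06, cr = 0.002),
      nf  = list(type = "inact", k = 6,   tau_max = 4,    Vp = -75, cl = 0.08, cr = 0.022),
      ns  = list(type = "inact", k = 6,   tau_max = 250,  Vp = -75, cl = 0.05, cr = 0.03),
      l   = list(type = "act",   k = 7,   Vh = -30,
                 tau_max = 2,    Vp = -25, cl = 0.02, cr = 0.03),
      lf  = list(type = "inact", k = 7,   tau_max = 20,   Vp = -20, cl = 0.06, cr = 0.035),
      ls  = list(type = "inact", k = 7,   tau_max = 150,  Vp = -20, cl = 0.04, cr = 0.02),
      kt  = list(type = "act",   k = 5,   tau_max = 3,    Vp = -25, cl = 0.05, cr = 0.01),
      ktf = list(type = "inact", k = 5,   tau_max = 10,   Vp = -10, cl = 0.02, cr = 0.007),
      kts = list(type = "inact", k = 5,   tau_max = 500,  Vp = -50, cl = 0.03, cr = 0.01),
      r   = list(type = "act",   k = 8,   tau_max = 100,  Vp = -60, cl = 0.04, cr = 0.02),
      ri  = list(type = "inact", k = 12,  tau_max = 8,    Vp = -60, cl = 0.04, cr = 0.04),
      ct  = list(type = "act",   k = 5.5, tau_max = 1.5,  Vp = -55, cl = 0.08, cr = 0.08),
      cti = list(type = "inact", k = 5,   tau_max = 15,   Vp = -75, cl = 0.06, cr = 0.06),
      s   = list(type = "act",   k = 10,  tau_max = 60,   Vp = -50, cl = 0.12, cr = 0.005),
      y   = list(type = "inact", k = 6,   tau_max = 1000, Vp = -90, cl = 0.03, cr = 0.03),
      Cai = list(type = "cdi",   a1 = 30, tau_const = 30))
  )
}

#' Default analysis conditions for the bundled rat model
#'
#' The stimulus protocol (a 528 pA, 7 ms current pulse starting at 60 ms,
#' which elicits a single action potential whose upstroke foot and peak sit
#' at about 67.4 and 71 ms), the phase-detection criteria calibrated for
#' this model's repolarisation slopes, and the dense analysis window.
#'
#' @return List with `protocol`, `criteria` and `window`.
#' @export
rat_analysis_defaults <- function() {
  list(protocol = stimulus_protocol(amplitude = 528, onset = 60,
                                    duration = 7, total_time = 5000,
                                    mode = "pulse"),
       criteria = phase_criteria(phase1_end_slope = -2,
                                 plateau_exit_slope = -1.8),
       window = c(50, 130))
}

#' Tabulated initial state of the rat model (30 components)
#' @export
rat_initial_state <- function() {
  c(V = -72,
    n = 0.0041, nf = 0.67, ns = 0.67,
    l = 2.1e-6, lf = 0.99, ls = 0.99, Cai = 0.99,
    kt = 0.0021, ktf = 0.98, kts = 0.64,
    r = 0.3657, ri = 0.1, ct = 0.089, cti = 0.081,
    s = 0.1776, y = 0.0035,
    Na_i = 10.73519, K_i = 139.275, Ca_i = 7.9e-5, Cl_i = 30.03,
    Ca_ss = 8.737212e-5, Ca_JSR = 6.607948e-2, Ca_NSR = 0.06600742,
    PC1 = 0.634, PO1 = 4.327e-4, PO2 = 6.06e-10, PC2 = 0.634,
    HTRPNCa = 0.139, LTRPNCa = 0.00516)
}

# two-sided exponential time-constant profile peaking near Vp
tau_bell <- function(tau_max, Vp, cl, cr) {
  b <- 1 / (2 * tau_max)
  list(c(b, cr, -cr * Vp), c(b, -cl, cl * Vp))
}

rat_gates <- function(params, init) {
  out <- list()
  for (nm in names(params$gating)) {
    gp <- params$gating[[nm]]
    x0 <- init[[nm]]
    if (identical(gp$type, "cdi")) {
      a2 <- log(1 / x0 - 1) - gp$a1 * init[["Ca_ss"]]
      out[[nm]] <- gate_spec(nm, ss = c(gp$a1, a2),
                             tau = list(c(1 / gp$tau_const, 0, 0)),
                             driver = "Ca_ss")
      next
    }
    a1 <- if (gp$type == "act") -1 / gp$k else 1 / gp$k
    # midpoint: explicit Vh when given, otherwise pinned so that the
    # tabulated initial value is the steady state at -72 mV
    a2 <- if (!is.null(gp$Vh)) -a1 * gp$Vh else log(1 / x0 - 1) + 72 * a1
    out[[nm]] <- gate_spec(nm, ss = c(a1, a2),
                           tau = tau_bell(gp$tau_max, gp$Vp, gp$cl, gp$cr))
  }
  out
}

rat_channels <- function(params) {
  g <- params$g
  K1p <- params$K1
  Ef <- params$E_fixed
  list(
    channel_spec("Na",  g[["Na"]], list(c("n", 3), c("nf", 1), c("ns", 1)), ion = "Na"),
    channel_spec("CaL", g[["CaL"]], list(c("l", 1), c("lf", 1), c("ls", 1), c("Cai", 1)),
                 ion = "Ca", E_fixed = Ef[["CaL"]]),
    channel_spec("CaT", g[["CaT"]], list(c("ct", 1), c("cti", 1)),
                 ion = "Ca", E_fixed = Ef[["CaT"]]),
    channel_spec("t0",  g[["t0"]], list(c("kt", 1), c("ktf", 1), c("kts", 1)), ion = "K"),
    channel_spec("K1",  g[["K1"]], ion = "K",
                 rectification = list(Vh = K1p$Vh, k = K1p$k)),
    channel_spec("Kr",  g[["Kr"]], list(c("r", 1), c("ri", 1)), ion = "K"),
    channel_spec("Ks",  g[["Ks"]], list(c("s", 1)), ion = "K"),
    channel_spec("f",   g[["f"]], list(c("y", 1)), E_fixed = Ef[["f"]]),
    channel_spec("BNa", g[["BNa"]], ion = "Na"),
    channel_spec("BK",  g[["BK"]], ion = "K"),
    channel_spec("BCa", g[["BCa"]], ion = "Ca"),
    channel_spec("Clb", g[["Clb"]], ion = "Cl"))
}

#' Sarcoplasmic-reticulum and buffering fluxes of the rat model
#'
#' RyR release, SERCA uptake, NSR->JSR transfer, subspace->myoplasm
#' transfer, troponin binding fluxes, RyR state transition rates and the
#' rapid-buffering factors, all in mM/ms (rates in 1/ms), evaluated at one
#' state.  Fluxes are formulated so that total calcium (free plus buffered,
#' volume-weighted) changes only through trans-sarcolemmal transport.
#'
#' @param state Named state vector (see [rat_initial_state()]).
#' @param params `rat_model_parameters()$ca` or the full parameter list.
#' @export
calcium_fluxes <- function(state, params = rat_model_parameters()) {
  p <- if (!is.null(params$ca)) params$ca else params
  conc <- state[c("Ca_i", "Ca_ss", "Ca_JSR", "Ca_NSR")]
  if (any(conc <= 0))
    stop("calcium_fluxes: non-positive concentration in ",
         paste(names(conc)[conc <= 0], collapse = ", "))
  Cai <- state[["Ca_i"]]; Cass <- state[["Ca_ss"]]
  CaJ <- state[["Ca_JSR"]]; CaN <- state[["Ca_NSR"]]
  Jrel <- p$v1 * (state[["PO1"]] + state[["PO2"]]) * (CaJ - Cass)
  Jtr <- (CaN - CaJ) / p$tau_tr
  Jxfer <- (Cass - Cai) / p$tau_xfer
  fb <- (Cai / p$Kfb)^p$Nfb
  rb <- (CaN / p$Krb)^p$Nrb
  Jup <- p$Ksr * (p$vmaxf * fb - p$vmaxr * rb) / (1 + fb + rb)
  dHT <- p$khtrpn_p * Cai * (p$HTRPNtot - state[["HTRPNCa"]]) -
    p$khtrpn_m * state[["HTRPNCa"]]
  dLT <- p$kltrpn_p * Cai * (p$LTRPNtot - state[["LTRPNCa"]]) -
    p$kltrpn_m * state[["LTRPNCa"]]
  ryr <- c(
    dPC1 = -p$ka_p * Cass^4 * state[["PC1"]] + p$ka_m * state[["PO1"]],
    dPO1 = p$ka_p * Cass^4 * state[["PC1"]] - p$ka_m * state[["PO1"]] -
      p$kb_p * Cass^3 * state[["PO1"]] + p$kb_m * state[["PO2"]] -
      p$kc_p * state[["PO1"]] + p$kc_m * state[["PC2"]],
    dPO2 = p$kb_p * Cass^3 * state[["PO1"]] - p$kb_m * state[["PO2"]],
    dPC2 = p$kc_p * state[["PO1"]] - p$kc_m * state[["PC2"]])
  beta_i <- 1 / (1 + p$CMDNtot * p$KmCMDN / (p$KmCMDN + Cai)^2 +
                   if (p$egta_enabled) p$EGTAtot * p$KmEGTA / (p$KmEGTA + Cai)^2 else 0)
  beta_ss <- 1 / (1 + p$CMDNtot * p$KmCMDN / (p$KmCMDN + Cass)^2)
  beta_JSR <- 1 / (1 + p$CSQNtot * p$KmCSQN / (p$KmCSQN + CaJ)^2)
  list(Jrel = Jrel, Jtr = Jtr, Jxfer = Jxfer, Jup = Jup,
       Jtrpn = dHT + dLT, dHTRPNCa = dHT, dLTRPNCa = dLT, ryr = ryr,
       beta_i = beta_i, beta_ss = beta_ss, beta_JSR = beta_JSR)
}

# pump and exchanger currents, pA (positive outward)
rat_pump_currents <- function(V, state, pumps, conc_out, constants) {
  vfrt <- V * constants$F / (constants$R * constants$T)
  Nai <- state[["Na_i"]]; Cai <- state[["Ca_i"]]
  Nao <- conc_out$Na_o; Cao <- conc_out$Ca_o; Ko <- conc_out$K_o
  sigma <- (exp(Nao / 67.3) - 1) / 7
  fNaK <- 1 / (1 + 0.1245 * exp_clamped(-0.1 * vfrt) +
                 0.0365 * sigma * exp_clamped(-vfrt))
  INaK <- pumps$INaK_max * fNaK * (Ko / (Ko + pumps$Km_Ko)) /
    (1 + (pumps$Km_Nai / Nai)^1.5)
  expe <- exp_clamped(pumps$eta * vfrt)
  expem1 <- exp_clamped((pumps$eta - 1) * vfrt)
  INaCa <- pumps$k_NaCa / (pumps$Km_Na^3 + Nao^3) / (pumps$Km_Ca + Cao) /
    (1 + pumps$k_sat * expem1) *
    (expe * Nai^3 * Cao - expem1 * Nao^3 * Cai)
  ICaP <- pumps$ICaP_max * Cai / (pumps$Km_CaP + Cai)
  c(INaK = INaK, INaCa = INaCa, ICaP = ICaP)
}

# The non-gating dynamics hook of the rat model: pump currents, ion
# bookkeeping and the calcium subsystem.  Allocation-lean: this runs once
# per right-hand-side evaluation inside the stiff solver.
rat_ca_handling <- function(t, y, ctx) {
  model <- ctx$model
  p <- model$params
  ix <- model$compiled$cache$rat_ix
  if (is.null(ix)) {
    ix <- match(.RAT_EXTRA_STATES, model$state_layout)
    model$compiled$cache$rat_ix <- ix
  }
  ca <- p$ca
  # numerical guard: implicit-solver probes may momentarily cross zero
  Cai <- max(y[ix[4L]], 1e-12); Cass <- max(y[ix[5L]], 1e-12)
  CaJ <- max(y[ix[6L]], 1e-12); CaN <- max(y[ix[7L]], 1e-12)
  PC1 <- y[ix[8L]]; PO1 <- y[ix[9L]]; PO2 <- y[ix[10L]]; PC2 <- y[ix[11L]]
  HT <- y[ix[12L]]; LT <- y[ix[13L]]
  Jrel <- ca$v1 * (PO1 + PO2) * (CaJ - Cass)
  Jtr <- (CaN - CaJ) / ca$tau_tr
  Jxfer <- (Cass - Cai) / ca$tau_xfer
  fb <- (Cai / ca$Kfb)^ca$Nfb
  rb <- (CaN / ca$Krb)^ca$Nrb
  Jup <- ca$Ksr * (ca$vmaxf * fb - ca$vmaxr * rb) / (1 + fb + rb)
  dHT <- ca$khtrpn_p * Cai * (ca$HTRPNtot - HT) - ca$khtrpn_m * HT
  dLT <- ca$kltrpn_p * Cai * (ca$LTRPNtot - LT) - ca$kltrpn_m * LT
  a_open <- ca$ka_p * Cass^4 * PC1; a_close <- ca$ka_m * PO1
  b_open <- ca$kb_p * Cass^3 * PO1; b_close <- ca$kb_m * PO2
  c_fwd <- ca$kc_p * PO1; c_back <- ca$kc_m * PC2
  beta_i <- 1 / (1 + ca$CMDNtot * ca$KmCMDN / (ca$KmCMDN + Cai)^2 +
                   if (ca$egta_enabled)
                     ca$EGTAtot * ca$KmEGTA / (ca$KmEGTA + Cai)^2 else 0)
  beta_ss <- 1 / (1 + ca$CMDNtot * ca$KmCMDN / (ca$KmCMDN + Cass)^2)
  beta_JSR <- 1 / (1 + ca$CSQNtot * ca$KmCSQN / (ca$KmCSQN + CaJ)^2)
  st <- c(Na_i = y[ix[1L]], Ca_i = Cai)
  Ip <- rat_pump_currents(ctx$V, st, p$pumps, model$concentrations,
                          model$constants)
  F <- model$constants$F
  I <- ctx$currents
  dNa <- -(I[["Na"]] + I[["BNa"]] + 3 * Ip[[1L]] + 3 * Ip[[2L]]) /
    (F * ca$Vmyo)
  dK <- -(I[["t0"]] + I[["K1"]] + I[["Kr"]] + I[["Ks"]] + I[["BK"]] -
            2 * Ip[[1L]]) / (F * ca$Vmyo)
  dCl <- I[["Clb"]] / (F * ca$Vmyo)
  dCai <- beta_i * (Jxfer * ca$Vss / ca$Vmyo - Jup - (dHT + dLT) -
                      (I[["BCa"]] + Ip[[3L]] - 2 * Ip[[2L]] +
                         I[["CaT"]]) / (2 * F * ca$Vmyo))
  dCass <- beta_ss * (Jrel * ca$VJSR / ca$Vss - Jxfer -
                        I[["CaL"]] / (2 * F * ca$Vss))
  deriv <- c(dNa, dK, dCl, dCai, dCass,
             beta_JSR * (Jtr - Jrel),
             Jup * ca$Vmyo / ca$VNSR - Jtr * ca$VJSR / ca$VNSR,
             a_close - a_open,
             a_open - a_close - b_open + b_close - c_fwd + c_back,
             b_open - b_close,
             c_fwd - c_back,
             dHT, dLT)
  names(deriv) <- .RAT_EXTRA_STATES
  list(currents = Ip, deriv = deriv)
}

.RAT_EXTRA_STATES <- c("Na_i", "K_i", "Cl_i", "Ca_i", "Ca_ss", "Ca_JSR",
                       "Ca_NSR", "PC1", "PO1", "PO2", "PC2", "HTRPNCa",
                       "LTRPNCa")

#' Build the bundled rat left-ventricular cardiomyocyte model
#'
#' Assembles the 30-state model: membrane potential, 16 gating variables, 8
#' gated ionic currents plus 4 background channels and the inward rectifier,
#' Na+/K+ pump, Na+/Ca2+ exchanger and sarcolemmal Ca2+ pump, intracellular
#' Na+/K+/Ca2+/Cl- bookkeeping, and the sarcoplasmic-reticulum calcium
#' subsystem (RyR four-state scheme, SERCA uptake, compartment transfer,
#' troponin/calmodulin/calsequestrin buffering).
#'
#' @param overrides Nested list merged over [rat_model_parameters()]
#'   (e.g. `list(pumps = list(INaK_max = 80))`).
#' @return A [cell_model()].
#' @export
build_rat_model <- function(overrides = list()) {
  params <- utils::modifyList(rat_model_parameters(), overrides)
  init <- rat_initial_state()
  cell_model("rat-lv-2021",
             gates = rat_gates(params, as.list(init)),
             channels = rat_channels(params),
             capacitance = params$capacitance,
             initial_state = init,
             constants = physical_constants(),
             concentrations = list(Na_o = 140, K_o = 5.4, Ca_o = 1.5,
                                   Cl_o = 140),
             extra_dynamics = "rat_ca_handling",
             params = params)
}
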