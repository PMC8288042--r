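---
title: "Regional contribution analysis of gating kinetics in cardiac action-potential models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional contribution analysis of gating kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question the method answers

A ventricular action potential (AP) emerges from the interplay of a dozen
voltage-gated currents, each governed by activation and inactivation gates
relaxing towards voltage-dependent steady states \(x_\infty(V)\) with
time constants \(\tau_x(V)\).  Asking *which* gate shapes *which part* of
the AP, and by *how much*, is not answerable by inspection once the model
is stiff and nonlinear.  `apcontrib` implements a perturbation measure of
that regional influence: scale one gate's time constant by a factor
\(1+\delta\) over a region of the trajectory, measure the fractional change
of the region's duration, and normalise by \(\delta\):

\[
C = \frac{(D' - D)/D}{\delta}.
\]

\(C\) is the elasticity of the region's duration with respect to the
gate's speed.  \(C > 0\) means slowing the gate prolongs the region;
\(C = 1\) means the duration is exactly proportional to the time constant,
the strongest possible control.

## Model form

Models are declarative Hodgkin–Huxley systems: each current is
\(I_Y = \bar g_Y\, a^M b^N c^L (V - E_{\mathrm{ion}})\) with non-negative
integer gate powers; each gate obeys
\(dx/dt = (x_\infty(V) - x)/\tau_x(V)\) with
\(x_\infty(V) = 1/(1 + e^{a_1 V + a_2})\) and
\(\tau_x(V) = 1/\sum_i b_i e^{c_i V + d_i}\).  The sum-of-exponentials
time-constant form accommodates bell-shaped and monotone profiles with any
number of terms; terms may carry negative weights provided the summed rate
stays positive over the physiological voltage range, which the constructors
verify on \([-120, 80]\) mV.  Reversal potentials are either fixed or
computed from the Nernst equation using instantaneous intracellular
concentrations when those are state variables.  Additional dynamics —
calcium handling, pump currents, ion bookkeeping — attach through a named
hook that contributes currents and state derivatives without touching the
gating core.

## Regions: phases, epochs, intervals of interest

The analysed AP is cut three ways:

* **Phases** P0–P4 follow the conventional electrophysiological
  nomenclature: depolarisation (P0–P1), early repolarisation (P1–P2),
  plateau (P2–P3) and late repolarisation/return (P3–P4).  Detection is
  slope-based: P0 is the last upward crossing of an upstroke threshold
  (1 mV/ms **above the baseline drift**, estimated as the median dV/dt over
  the approach window before the maximal upstroke velocity, so that a
  stimulus-driven subthreshold ramp cannot mask the take-off); P1 is the
  voltage maximum; P2 the first recovery of dV/dt above the
  phase-1-end threshold, provided rapid repolarisation begins within 2 ms of
  the peak (otherwise P2 collapses onto P1); P3 the first sustained drop
  below the plateau-exit threshold; and P4 the return to within 2 mV of the
  pre-stimulus baseline, with 99 %-repolarisation and settling fallbacks for
  protocols that hold the membrane away from rest.  All five points accept
  explicit user overrides, since phase conventions are ultimately a choice.
* **Epochs** are the atomic measurement intervals: sub-intervals bounded by
  the phase points, the inflection points (curvature sign changes) of V and
  of the gate's own trajectory, and the local extrema of V.  Adding the
  extrema guarantees V is monotone inside each epoch, which makes "the time
  at which the perturbed run reaches the reference end voltage" well
  defined.  Epochs shorter than `min_epoch_ms` (default 0.05 ms) are merged
  into their shorter neighbour, because measuring a perturbation on a
  sliver amplifies numerical error without adding information.
* **Intervals of interest (IoIs)** are four equal quarters of each phase.
  IoI and APD-region values pool the epochs lying under the region: epochs
  are cut at region boundaries, every cut segment is measured by its own
  perturbation run, and segments pool by total duration,
  \(C = \frac{\sum_k \Delta D_k}{\sum_k D_k}/\delta\).  Phase totals instead
  sum the per-epoch normalised contributions \(\sum_k C_k\); the two
  aggregation rules deliberately coexist (a sum of ratios is not a pooled
  ratio) and every result records which was used.

Curvature sign changes use central differences with a widened stencil on
dense grids and a tolerance band (defaults `tol_V = 2e-4` and
`tol_gate = 2e-4` per unit of trace amplitude): a crossing counts only if
the curvature leaves the band on both sides, which suppresses the
floating-point wiggle a stiff solver leaves on near-flat plateau segments.

## The perturbed-duration measurement

Each epoch's measurement restarts the model from the reference state at the
epoch start with \(\tau_{\text{gate}}\) multiplied by \(1+\delta\) for the
whole run (a slowed rate law, not a one-off state kick), and integrates
until V crosses the reference end voltage.  Two details matter:

* **Extremum-terminated epochs.**  An epoch ending at the AP peak cannot
  always be measured by a voltage crossing: if the perturbation weakens the
  upstroke, the perturbed trajectory peaks *below* the reference end
  voltage.  The crossing is attempted first (a perturbation that
  strengthens the AP passes the reference peak voltage on its way up, and
  the early crossing correctly yields a negative contribution); only when
  no crossing exists within a short horizon does the measurement fall back
  to the perturbed trajectory's own extremum (the root of dV/dt), the
  corresponding event on the perturbed time axis.
* **Independence.**  Every epoch restarts from the *reference* state, so
  contributions are local: no perturbation effect carries over between
  epochs.

`delta` defaults to 0.10 — large enough that duration changes sit well
above solver error, small enough to stay in the near-linear regime.  A
diagnostic check with `delta = 0.05` should agree in sign; the package's
tests enforce that on the bundled model.  `delta = 0` is the identity and
returns the reference duration without re-integration.

The sign convention follows from the direction of the gating curve, the
direction of V and the sign of the channel's reversal potential: same
direction with a positive reversal gives a positive contribution, opposite
directions a negative one, and both flip for potassium.  `expected_sign()`
implements the rule and `run_full_analysis()` attaches a per-gate,
per-phase comparison of predicted versus measured sign.

## Numerics

The systems are stiff (time scales from ~0.05 ms sodium activation to
~1 s pacemaker gating), so integration uses the variable-order BDF (Gear)
family via `deSolve`, with `rtol = 1e-8`, `atol = 1e-10` by default:
contributions are small ratios of durations, and the integration error must
sit one or more orders below the measured effects.  Stimulus
discontinuities restart the integrator so the multistep history never
straddles a current step.  Event stops use `lsodar` root finding on
\(V - V_{\text{target}}\) (or on dV/dt in the extremum fallback).  Dense
output grids default to 0.001 ms (0.0001 ms for high-precision
segmentation); the package's stability test verifies that phase-level
contributions computed on the two grids agree closely, and analytic
fixtures verify the measurement chain end-to-end: a single-gate threshold
model whose event time is exactly proportional to \(\tau\) must return
\(C = 1\) to \(10^{-6}\) for any \(\delta\), and a gate decoupled from every
current must return \(C = 0\) to \(10^{-9}\).

## The bundled rat left-ventricular model

The package ships a 30-state adult rat left-ventricular myocyte model:
membrane potential; 16 gating variables (Na⁺ activation `n` and fast/slow
inactivation `nf`, `ns`; L-type Ca²⁺ `l`, `lf`, `ls` and the
Ca²⁺-dependent inactivation gate `Cai`, driven by subspace calcium rather
than voltage; T-type `ct`, `cti`; transient outward `kt`, `ktf`, `kts`;
rapid and slow delayed rectifiers `r`, `ri`, `s`; hyperpolarisation-activated
`y`); intracellular Na⁺/K⁺/Ca²⁺/Cl⁻; subspace, junctional- and
network-SR calcium; a four-state ryanodine-receptor scheme; and two
troponin buffers.  Calmodulin and calsequestrin buffering use the rapid
approximation.  Pump and exchanger currents (Na⁺/K⁺ pump, Na⁺/Ca²⁺
exchanger, sarcolemmal Ca²⁺ pump) close the ion budgets; they are
time-independent and therefore outside what the perturbation measure can
address, by construction.

**Provenance.**  The channel maximal conductances, the complete calcium
handling/buffering parameter set, the physical constants, the 30-component
initial state and the extracellular concentrations are taken verbatim from
the published parameter tables of the source model family.  The gating
kinetics themselves (sigmoid slopes and midpoints, time-constant profiles),
the pump magnitudes, the inward-rectifier shape of IK1 and the fixed
reversal potentials of the CaL/CaT/f channels are **package-calibrated
(synthetic)**: the full fitted coefficient set of the source model is not
publicly tabulated.  The calibration pins each sigmoid midpoint so that the
tabulated initial state is the resting steady state at −72 mV (except the
L-type activation midpoint, set explicitly at −30 mV), and chooses
time-constant profiles within measured rat ranges such that the model
reproduces adult-rat AP morphology: a quiescent rest, a single AP on a
suprathreshold pulse with peak between 30 and 50 mV, an upstroke
completed within milliseconds, and APD90 of roughly 50 ms.  The
packaged model file is named `rat-lv-2021-synthetic.yaml` to make the
synthetic component explicit.

**Protocol.**  The default analysis protocol (`rat_analysis_defaults()`)
is a 528 pA, 7 ms current pulse starting at 60 ms.  With whole-cell
conductances in nS, a *sustained* 528 pA injection would hold the 100 pF
cell permanently depolarised (total available outward current below
−40 mV is well under the injected current), so the sustained mode cannot
produce a repolarised late phase; the pulse mode is the physiologically
standard pacing protocol and elicits an AP whose upstroke foot and peak
fall at about 67.5 and 71 ms.  The phase-detection thresholds calibrated
for this model's repolarisation slopes are `phase1_end_slope = -2` and
`plateau_exit_slope = -1.8` mV/ms.

**What passing tests do and do not show.**  Because the gating coefficients
are synthetic, agreement with the source model is structural, not numeric:
the analysis reproduces the dominance pattern (sodium activation dominating
depolarisation with positive sign and the inactivation gates opposing it;
the transient outward activation driving early repolarisation; L-type
calcium activation and the slow delayed rectifier shaping the plateau with
positive contributions; the deactivating slow rectifier turning negative in
late repolarisation), but the printed contribution magnitudes of the
original differ where they depend on the unpublished kinetics.  Results on
this model demonstrate the method, not the original parameter fit.

**Known deviations recorded here.**  The body text of the source describes
32 state equations while its initial-condition table lists 30 values; the
table is authoritative for this package, so the model has 30 states.  The
two tabulated ryanodine-receptor closed-state occupancies are equal (0.634
each) and the four RyR states sum to ≈1.27, not 1; the values are taken
verbatim and the occupancy sum is deliberately not normalised.  The
conductance unit label in the source's unit table (nS/pF) is treated as
whole-cell nS, the only reading that yields physiological current
magnitudes.  The EGTA buffer parameters are carried in the parameter set
but disabled by default, EGTA being a voltage-clamp-protocol chelator.
The membrane capacitance, absent from the tables, defaults to 100 pF.

## Problem sizes and runtimes

The shipped analyses use a dense window of 80 ms around the AP at a 0.001
ms output grid (~80,000 samples, 30 state columns), with the
high-precision stability comparison at 0.0001 ms restricted to the same
window.  A full regional table for one gate costs one reference simulation
plus roughly 30–60 short perturbed integrations; the six-gate headline
analysis completes in a few minutes on a single core.

## Limitations

* Contributions of time-independent currents (pumps, exchangers,
  background leaks) are invisible to the measure by construction.
* Near a voltage extremum the reference trajectory is tangential to the
  stopping level, so epoch contributions there are intrinsically
  high-gain; the extremum fallback keeps them finite and well defined, but
  their magnitudes are the most sensitive numbers the method produces.
* Multi-beat trains, alternans and arrhythmic morphologies (EADs/DADs) are
  out of scope for the segmenter, which assumes a single AP per analysis
  window.
* The synthetic rat kinetics reproduce morphology and dominance structure,
  not the source model's exact fitted coefficients; see the provenance
  notes above.
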