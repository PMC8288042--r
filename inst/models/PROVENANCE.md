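# Provenance of the bundled rat left-ventricular model (`rat-lv-2021`)

Component-by-component audit of `rat-lv-2021-synthetic.yaml` /
`build_rat_model()`. "Published tables" below means the printed parameter
tables of the source model family this implementation follows; "synthetic"
means package-calibrated values, chosen so the assembled model reproduces
adult-rat left-ventricular AP morphology (quiescent rest near −72 mV, a
single pulse-elicited AP peaking between 30 and 50 mV, APD90 ≈ 50 ms).

| Component | Status | Notes |
|---|---|---|
| Channel maximal conductances (gNa … gBCa, 12 values) | published tables, verbatim | interpreted as whole-cell nS; the unit table's "nS/pF" label is physically inconsistent with the printed magnitudes |
| Physical constants (F, T, R) | published tables, verbatim | R in mJ/(mol K) so Nernst yields mV |
| SR/buffering parameters (v1, Kfb, Krb, Ksr, Nfb, Nrb, vmaxf, vmaxr, τtr, τxfer, ka±, kb±, kc±, k(h/l)trpn±, CMDN/CSQN/HTRPN/LTRPN totals and Km's, volumes, Acap) | published tables, verbatim | flux equations in the four-compartment Winslow-style form |
| EGTA parameters (EGTAtot, KmEGTA) | published tables, verbatim | carried but disabled by default (voltage-clamp chelator) |
| Initial state (30 components) | published tables, verbatim | the source text says 32 equations but tabulates 30 initial values; the table wins. Both RyR closed states are 0.634 as printed; the RyR occupancy sum (≈1.27) is deliberately not normalised |
| Extracellular concentrations (Na 140, K 5.4, Ca 1.5, Cl 140 mM) | published tables, verbatim | |
| Gating steady-state coefficients (a1, a2 per gate) | synthetic | midpoints pinned so the tabulated initial value is the −72 mV steady state, except L-type activation (explicit midpoint −30 mV); slopes in measured rat ranges |
| Gating time-constant coefficients (b, c, d per gate) | synthetic | two-sided exponential profiles; peaks and wings calibrated to the AP morphology above |
| Ca²⁺-dependent inactivation gate (`Cai`) | synthetic | driven by subspace Ca²⁺, mild sensitivity (a1 = 30 /mM), τ = 30 ms |
| IK1 inward rectification (midpoint −52 mV, slope 6 mV) | synthetic | instantaneous sigmoid conductance scale |
| Pump/exchanger parameters (INaK, INaCa, ICaP) | synthetic | standard Luo-Rudy/Winslow formulations, magnitudes set for resting ion balance |
| Fixed reversal potentials (E_CaL = 65, E_CaT = 50, E_f = −20 mV) | synthetic | standard rat-model choices |
| Membrane capacitance (100 pF) | synthetic | standard adult rat LV value; not printed in the tables |
| Stimulus protocol (528 pA) | published value | amplitude as printed; the bundled analysis uses the 7 ms pulse mode at onset 60 ms (see the methods vignette for why a sustained injection cannot repolarise with nS-scale conductances) |
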