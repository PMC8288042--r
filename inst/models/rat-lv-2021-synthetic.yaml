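name: rat-lv-2021
capacitance: 100.0
constants:
  F: 96487.0
  T: 310.15
  R: 8314.0
concentrations:
  Na_o: 140.0
  K_o: 5.4
  Ca_o: 1.5
  Cl_o: 140.0
gates:
  'n':
    name: 'n'
    ss:
    - -0.181818181818
    - -7.598249213682
    tau:
    - - 1.25
      - 0.002
      - 0.084
    - - 1.25
      - -0.06
      - -2.52
    driver: V
  nf:
    name: nf
    ss:
    - 0.166666666667
    - 11.291814942076
    tau:
    - - 0.125
      - 0.022
      - 1.65
    - - 0.125
      - -0.08
      - -6.0
    driver: V
  ns:
    name: ns
    ss:
    - 0.166666666667
    - 11.291814942076
    tau:
    - - 0.002
      - 0.03
      - 2.25
    - - 0.002
      - -0.05
      - -3.75
    driver: V
  l:
    name: l
    ss:
    - -0.142857142857
    - -4.285714285714
    tau:
    - - 0.25
      - 0.03
      - 0.75
    - - 0.25
      - -0.02
      - -0.5
    driver: V
  lf:
    name: lf
    ss:
    - 0.142857142857
    - 5.69059443558
    tau:
    - - 0.025
      - 0.035
      - 0.7
    - - 0.025
      - -0.06
      - -1.2
    driver: V
  ls:
    name: ls
    ss:
    - 0.142857142857
    - 5.69059443558
    tau:
    - - 0.003333333333
      - 0.02
      - 0.4
    - - 0.003333333333
      - -0.04
      - -0.8
    driver: V
  kt:
    name: kt
    ss:
    - -0.2
    - -8.236284273839
    tau:
    - - 0.166666666667
      - 0.01
      - 0.25
    - - 0.166666666667
      - -0.05
      - -1.25
    driver: V
  ktf:
    name: ktf
    ss:
    - 0.2
    - 10.508179701889
    tau:
    - - 0.05
      - 0.007
      - 0.07
    - - 0.05
      - -0.02
      - -0.2
    driver: V
  kts:
    name: kts
    ss:
    - 0.2
    - 13.824635855096
    tau:
    - - 0.001
      - 0.01
      - 0.5
    - - 0.001
      - -0.03
      - -1.5
    driver: V
  r:
    name: r
    ss:
    - -0.125
    - -8.449291296515
    tau:
    - - 0.005
      - 0.02
      - 1.2
    - - 0.005
      - -0.04
      - -2.4
    driver: V
  ri:
    name: ri
    ss:
    - 0.083333333333
    - 8.197224577336
    tau:
    - - 0.0625
      - 0.04
      - 2.4
    - - 0.0625
      - -0.04
      - -2.4
    driver: V
  ct:
    name: ct
    ss:
    - -0.181818181818
    - -10.765002563381
    tau:
    - - 0.333333333333
      - 0.08
      - 4.4
    - - 0.333333333333
      - -0.08
      - -4.4
    driver: V
  cti:
    name: cti
    ss:
    - 0.2
    - 16.828836967683
    tau:
    - - 0.033333333333
      - 0.06
      - 4.5
    - - 0.033333333333
      - -0.06
      - -4.5
    driver: V
  s:
    name: s
    ss:
    - -0.1
    - -5.667306935857
    tau:
    - - 0.008333333333
      - 0.005
      - 0.25
    - - 0.008333333333
      - -0.12
      - -6.0
    driver: V
  'y':
    name: 'y'
    ss:
    - 0.166666666667
    - 17.651486171157
    tau:
    - - 0.0005
      - 0.03
      - 2.7
    - - 0.0005
      - -0.03
      - -2.7
    driver: V
  Cai:
    name: Cai
    ss:
    - 30.0
    - -4.597741013735
    tau:
    - - 0.033333333333
      - 0.0
      - 0.0
    driver: Ca_ss
channels:
- name: Na
  g: 1004.4
  gates:
  - - 'n'
    - 3
  - - nf
    - 1
  - - ns
    - 1
  ion: Na
- name: CaL
  g: 6.2894
  gates:
  - - l
    - 1
  - - lf
    - 1
  - - ls
    - 1
  - - Cai
    - 1
  ion: Ca
  E_fixed: 65.0
- name: CaT
  g: 1.5854
  gates:
  - - ct
    - 1
  - - cti
    - 1
  ion: Ca
  E_fixed: 50.0
- name: t0
  g: 6.4718
  gates:
  - - kt
    - 1
  - - ktf
    - 1
  - - kts
    - 1
  ion: K
- name: K1
  g: 6.0
  gates: []
  ion: K
  rectification:
    Vh: -52.0
    k: 6.0
- name: Kr
  g: 5.7017
  gates:
  - - r
    - 1
  - - ri
    - 1
  ion: K
- name: Ks
  g: 6.4916
  gates:
  - - s
    - 1
  ion: K
- name: f
  g: 7.7282
  gates:
  - - 'y'
    - 1
  E_fixed: -20.0
- name: BNa
  g: 0.0326
  gates: []
  ion: Na
- name: BK
  g: 0.05
  gates: []
  ion: K
- name: BCa
  g: 0.0025
  gates: []
  ion: Ca
- name: Clb
  g: 1.5278
  gates: []
  ion: Cl
initial_state:
  V: -72.0
  'n': 0.0041
  nf: 0.67
  ns: 0.67
  l: 2.1e-06
  lf: 0.99
  ls: 0.99
  Cai: 0.99
  kt: 0.0021
  ktf: 0.98
  kts: 0.64
  r: 0.3657
  ri: 0.1
  ct: 0.089
  cti: 0.081
  s: 0.1776
  'y': 0.0035
  Na_i: 10.73519
  K_i: 139.275
  Ca_i: 7.9e-05
  Cl_i: 30.03
  Ca_ss: 8.737212e-05
  Ca_JSR: 0.06607948
  Ca_NSR: 0.06600742
  PC1: 0.634
  PO1: 0.0004327
  PO2: 6.06e-10
  PC2: 0.634
  HTRPNCa: 0.139
  LTRPNCa: 0.00516
extra_dynamics: rat_ca_handling
params:
  capacitance: 100.0
  g:
  - 1004.4
  - 6.4718
  - 7.7282
  - 6.0
  - 5.7017
  - 6.2894
  - 6.4916
  - 1.5854
  - 1.5278
  - 0.0326
  - 0.05
  - 0.0025
  ca:
    v1: 10.5921
    Kfb: 0.00096176
    Krb: 28.1467
    Ksr: 2.3974
    Nfb: 1.2
    Nrb: 1.0
    vmaxf: 4.0e-05
    vmaxr: 0.0009
    tau_tr: 0.9258
    tau_xfer: 0.5234
    ka_p: 5780000.0
    ka_m: 0.5128
    kb_p: 21586000.0
    kb_m: 3.4472
    kc_p: 0.0513
    kc_m: 0.0062
    khtrpn_p: 43.1286
    khtrpn_m: 0.00071033
    kltrpn_p: 0.0969
    kltrpn_m: 0.0013
    HTRPNtot: 0.14
    LTRPNtot: 0.07
    CMDNtot: 0.05
    KmCMDN: 0.00238
    CSQNtot: 15.0
    KmCSQN: 0.8
    EGTAtot: 10.0
    KmEGTA: 0.00015
    egta_enabled: no
    Vmyo: 9.36
    VJSR: 0.056
    Vss: 0.0012
    VNSR: 0.504
    Acap: 0.8004
  pumps:
    INaK_max: 60.0
    Km_Nai: 10.0
    Km_Ko: 1.5
    k_NaCa: 8000.0
    Km_Na: 87.5
    Km_Ca: 1.38
    k_sat: 0.1
    eta: 0.35
    ICaP_max: 8.0
    Km_CaP: 0.0005
  K1:
    Vh: -52.0
    k: 6.0
  E_fixed:
  - 65.0
  - 50.0
  - -20.0
  gating:
    'n':
      type: act
      k: 5.5
      tau_max: 0.4
      Vp: -42.0
      cl: 0.06
      cr: 0.002
    nf:
      type: inact
      k: 6.0
      tau_max: 4.0
      Vp: -75.0
      cl: 0.08
      cr: 0.022
    ns:
      type: inact
      k: 6.0
      tau_max: 250.0
      Vp: -75.0
      cl: 0.05
      cr: 0.03
    l:
      type: act
      k: 7.0
      Vh: -30.0
      tau_max: 2.0
      Vp: -25.0
      cl: 0.02
      cr: 0.03
    lf:
      type: inact
      k: 7.0
      tau_max: 20.0
      Vp: -20.0
      cl: 0.06
      cr: 0.035
    ls:
      type: inact
      k: 7.0
      tau_max: 150.0
      Vp: -20.0
      cl: 0.04
      cr: 0.02
    kt:
      type: act
      k: 5.0
      tau_max: 3.0
      Vp: -25.0
      cl: 0.05
      cr: 0.01
    ktf:
      type: inact
      k: 5.0
      tau_max: 10.0
      Vp: -10.0
      cl: 0.02
      cr: 0.007
    kts:
      type: inact
      k: 5.0
      tau_max: 500.0
      Vp: -50.0
      cl: 0.03
      cr: 0.01
    r:
      type: act
      k: 8.0
      tau_max: 100.0
      Vp: -60.0
      cl: 0.04
      cr: 0.02
    ri:
      type: inact
      k: 12.0
      tau_max: 8.0
      Vp: -60.0
      cl: 0.04
      cr: 0.04
    ct:
      type: act
      k: 5.5
      tau_max: 1.5
      Vp: -55.0
      cl: 0.08
      cr: 0.08
    cti:
      type: inact
      k: 5.0
      tau_max: 15.0
      Vp: -75.0
      cl: 0.06
      cr: 0.06
    s:
      type: act
      k: 10.0
      tau_max: 60.0
      Vp: -50.0
      cl: 0.12
      cr: 0.005
    'y':
      type: inact
      k: 6.0
      tau_max: 1000.0
      Vp: -90.0
      cl: 0.03
      cr: 0.03
    Cai:
      type: cdi
      a1: 30.0
      tau_const: 30.0
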