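circulation:
  R_ao: 10.0
  R_ap: 480.744
  R_ad: 571.206
  R_ven: 60.0
  R_mv: 10.0
  C_ap: 0.863917
  C_ad: 0.14
  C_ven: 50.0
  V_ap0: 540.0
  V_ad0: 100.0
  V_ven0: 3231.99
  E_es_LA: 0.35
  V_LA0: 10.0
  A_LA: 0.35
  B_LA: 0.035
  T_max_LA: 150.0
  tau_LA: 25.0
  cycle_length: 800.0
lv:
  V_cav0: 72.2189
  V_wall: 68.3051
  n_shells: 24.0
  C_f: 1.83548
  b_f: 9.5
  T_max: 130.0
  Ca0: 4.35
  Ca0_max: 4.35
  B: 4.75
  l0: 1.58
  l_ref: 1.85
  t0: 275.0
  tau: 25.0
  T_trans: 275.0
network:
  root_D: 160.0
  terminal_D: 12.0
  area_ratio: 1.2
  k_LD: 20.0
  jitter_sd: 0.12
  D_min: 6.0
  Ap_scale: 0.6
  Bp_scale: 0.35
  phi_p: 70.0
  Cp: 30.0
  P_ref_cal: 100.0
  mu: 2.7e-09
initial:
  V_LA: 60.0
  V_LV: 229.161
  V_ap: 660.0
  V_ad: 113.0
  V_ven: 3800.0
simulation:
  dt: 1.0
  max_cycles: 10.0
  convergence_tol: 0.001
  n_sub: 5.0
  depths:
  - 0.0
  - 0.3333333
  - 0.6666667
  - 1.0
  n_networks: 4.0
  n_bif: 195.0
  n_trif: 3.0
  network_seed: 1.0
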