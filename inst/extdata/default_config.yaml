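membrane:
  tau_post: 8.0
  V_rest: -70.0
  R_m: 2960.0
ampar:
  g_AMPA0: 0.4
  V_AMPA: 0.0
  alpha: 1.1
  beta: 0.19
  P_half: 40.0
  k_half: 0.4
nmdar:
  V_NMDA: 0.0
  alpha: 0.164
  beta: 0.0066
  g_VI: 0.0075
  tau_g: 150.0
  k_slope: 0.212
  V0: -56.0
  Mg_out: 1.0
  k0: 9.83
  z: 2.0
  delta: 0.415
  Temp: 308.0
vgcc:
  g_R: 15.0
  V_R: 27.4
  'N': 80
  Vh_open: -49.2
  k_open: 1.39
calcium:
  eta: 0.012
  gamma: 0.06
  Z_ca: 2.0
  V_spine: 0.9048
  b_t: 200.0
  K_endo: 10.0
  K_s: 100.0
  c_rest: 0.1
cascade:
  e_p0: 0.1
  I_0: 0.1
  k3: 1.0
  k4: 0.001
  v_CaN: 2.0
  v_PKA: 0.45
  K_H2: 0.7
  k1: 0.5
  K_H1: 4.0
  K_M: 20.0
  k2: 10.0
  camkii_total: 100.0
opioid:
  Op: 0.0
  conductance_effect: yes
  mg_effect: yes
  vgcc: yes
  nmdar_coeff: 1.0
  vgcc_coeff: 1.0
  form: saturating
stimulus:
  frequency: 5.0
  pulse_width: 4.0
  amplitude: 0.2
  duration: 10.0
simulation:
  dt: 0.05
  t_end: 10.0
  seed: ~
  record_stride: 20
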