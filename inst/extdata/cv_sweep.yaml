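# Canonical p-Si/SiO2 EISCAP, C-V curves for a family of coverages of
# positively charged nanoparticles (delta_phi = +40 mV in the covered region).
device:
  eps_ir: 3.9
  d_i_nm: 35
  eps_sr: 11.7
  N_a_per_cm3: 2.76e15
  n_i_per_cm3: 1.5e10
  T_K: 300
  A_cm2: 0.5
  V_ip_V: 0
  phi_0_mV: -10
layer:
  coverage: 0.25
  delta_phi_mV: 40
run:
  mode: cv
  v_min_mV: -500
  v_max_mV: 1500
  grid_mV: 1
  coverages: [0, 0.25, 0.5, 0.75, 0.9]
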