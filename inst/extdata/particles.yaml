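# Synthetic hard-disk particle field emulating an SEM patch: 28 nm cores
# on a 1 um x 1 um area at the highest coverage reached in the incubation
# series (0.36 after 2 h).
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
run:
  mode: particles
  patch_width_nm: 1000
  patch_height_nm: 1000
  target_coverage: 0.36
  diameter_nm: 28
  seed: 42
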