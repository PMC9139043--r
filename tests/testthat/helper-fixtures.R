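# canonical p-Si/SiO2 device and decorations used across the suite
ref_device <- function(...) si_sio2_device(...)

ref_layer <- function(n, dphi_mV = 40) {
  nanoparticle_layer(coverage = n, delta_phi_mV = dphi_mV)
}

# independent re-derivation of the per-area series reciprocal capacitance,
# written from the device-physics identity 1/C = 1/C_i0 + w/eps_s rather
# than the package's closed form
oracle_S <- function(x, eps_ir = 3.9, d_i = 35e-9, eps_sr = 11.7,
                     Na_cm3 = 2.76e15, q = 1.6e-19, eps0 = 8.854e-12) {
  Ci0 <- eps0 * eps_ir / d_i
  eps_s <- eps0 * eps_sr
  sqrt(1 / Ci0^2 + 2 * x / (q * eps_s * Na_cm3 * 1e6))
}
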