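#' Physical constants used by the device model
#'
#' Returns the set of physical constants the capacitance model evaluates with.
#' Defaults are the values conventionally used in device-physics teaching
#' texts (three significant figures); they can be overridden, e.g. to switch
#' to full-precision CODATA values, and travel with the device object so that
#' every derived quantity uses one consistent set.
#'
#' @param q_C elementary charge (coulombs).
#' @param k_J_K Boltzmann constant (joules per kelvin).
#' @param eps0_F_m vacuum permittivity (farads per metre).
#' @return A named list with components `q`, `k`, `eps0`.
#' @examples
#' physical_constants()
#' physical_constants(q_C = 1.602176634e-19)
#' @export
physical_constants <- function(q_C = 1.6e-19, k_J_K = 1.38e-23,
                               eps0_F_m = 8.854e-12) {
  stopifnot(is.numeric(q_C), q_C > 0,
            is.numeric(k_J_K), k_J_K > 0,
            is.numeric(eps0_F_m), eps0_F_m > 0)
  list(q = q_C, k = k_J_K, eps0 = eps0_F_m)
}
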