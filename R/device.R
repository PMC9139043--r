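#' Semiconductor parameters
#'
#' Describes the p-type semiconductor substrate of an EISCAP. Values are
#' accepted in the units customary in the device literature (doping and
#' intrinsic carrier densities in cm^-3) and stored internally in SI (m^-3);
#' the original input values are retained so that re-exported parameters are
#' bit-identical to what was entered.
#'
#' @param eps_r relative permittivity of the semiconductor (dimensionless,
#'   > 1; 11.7 for silicon).
#' @param N_a_per_cm3 ionized-acceptor density (cm^-3).
#' @param n_i_per_cm3 intrinsic carrier density (cm^-3); must be below
#'   `N_a_per_cm3`.
#' @param T_K absolute temperature (kelvin).
#' @return An object of class `semiconductor_params`.
#' @examples
#' semiconductor_params(11.7, N_a_per_cm3 = 2.76e15, n_i_per_cm3 = 1.5e10)
#' @export
semiconductor_params <- function(eps_r, N_a_per_cm3, n_i_per_cm3,
                                 T_K = 300) {
  stopifnot(is.numeric(eps_r), length(eps_r) == 1,
            is.numeric(N_a_per_cm3), length(N_a_per_cm3) == 1,
            is.numeric(n_i_per_cm3), length(n_i_per_cm3) == 1,
            is.numeric(T_K), length(T_K) == 1)
  if (eps_r <= 1) stop("semiconductor relative permittivity must exceed 1")
  if (n_i_per_cm3 <= 0) stop("intrinsic density n_i must be positive")
  if (N_a_per_cm3 <= n_i_per_cm3)
    stop("acceptor density N_a must exceed the intrinsic density n_i")
  if (T_K <= 0) stop("temperature must be positive (kelvin)")
  structure(
    list(eps_r = eps_r,
         N_a = N_a_per_cm3 * 1e6,   # m^-3
         n_i = n_i_per_cm3 * 1e6,   # m^-3
         T = T_K,
         io = list(N_a_per_cm3 = N_a_per_cm3, n_i_per_cm3 = n_i_per_cm3)),
    class = "semiconductor_params")
}

#' Gate-insulator parameters
#'
#' @param eps_r relative permittivity of the gate insulator (>= 1; 3.9 for
#'   thermally grown SiO2).
#' @param d_nm insulator thickness (nanometres).
#' @return An object of class `insulator_params`.
#' @examples
#' insulator_params(3.9, d_nm = 35)
#' @export
insulator_params <- function(eps_r, d_nm) {
  stopifnot(is.numeric(eps_r), length(eps_r) == 1,
            is.numeric(d_nm), length(d_nm) == 1)
  if (eps_r < 1) stop("insulator relative permittivity must be >= 1")
  if (d_nm <= 0) stop("insulator thickness must be positive")
  structure(
    list(eps_r = eps_r,
         d = d_nm * 1e-9,           # m
         io = list(d_nm = d_nm)),
    class = "insulator_params")
}

#' Interfacial potentials of the particle-free surface
#'
#' Groups the gate-voltage offsets that do not depend on the nanoparticle
#' decoration: the lumped particle-independent potential `V_ip` (reference
#' electrode potential, solvent dipole potential, semiconductor work
#' function and fixed oxide/interface charge, combined) and the
#' insulator-electrolyte interfacial potential `phi_0` of the bare region.
#' An optional four-component decomposition of `V_ip` may be attached as
#' metadata; when present it must sum to `V_ip`.
#'
#' @param phi_0_mV interfacial potential of the nanoparticle-free region
#'   (millivolts).
#' @param V_ip_V lumped particle-independent potential (volts). Defaults to
#'   0, the convention used when simulating relative signal shifts.
#' @param decomposition optional named list with components `E_ref_V`,
#'   `chi_sol_V`, `phi_s_over_q_V`, `Q_over_Ci_V` (volts each) satisfying
#'   `E_ref + chi_sol - phi_s/q + (Q_i+Q_ss)/C_i = V_ip` to 1e-12 V.
#' @return An object of class `interface_potentials`.
#' @seealso [lumped_interface_voltage()]
#' @export
interface_potentials <- function(phi_0_mV, V_ip_V = 0, decomposition = NULL) {
  stopifnot(is.numeric(phi_0_mV), length(phi_0_mV) == 1,
            is.numeric(V_ip_V), length(V_ip_V) == 1)
  if (!is.null(decomposition)) {
    need <- c("E_ref_V", "chi_sol_V", "phi_s_over_q_V", "Q_over_Ci_V")
    if (!all(need %in% names(decomposition)))
      stop("decomposition must name: ", paste(need, collapse = ", "))
    s <- lumped_interface_voltage(decomposition$E_ref_V,
                                  decomposition$chi_sol_V,
                                  decomposition$phi_s_over_q_V,
                                  decomposition$Q_over_Ci_V)
    if (abs(s - V_ip_V) > 1e-12)
      stop(sprintf("decomposition sums to %g V but V_ip = %g V", s, V_ip_V))
  }
  structure(
    list(V_ip = V_ip_V,
         phi_0 = phi_0_mV * 1e-3,   # V
         decomposition = decomposition,
         io = list(phi_0_mV = phi_0_mV)),
    class = "interface_potentials")
}

#' Full EISCAP device description
#'
#' Bundles semiconductor, insulator, contact area, interfacial potentials
#' and the physical constants into one device object consumed by the C-V and
#' ConCap routines.
#'
#' @param semiconductor a [semiconductor_params()] object.
#' @param insulator an [insulator_params()] object.
#' @param A_cm2 electrolyte-contact area of the device (cm^2).
#' @param interface an [interface_potentials()] object.
#' @param constants physical constants, see [physical_constants()].
#' @return An object of class `eiscap_device`.
#' @examples
#' dev <- device_params(
#'   semiconductor_params(11.7, 2.76e15, 1.5e10, T_K = 300),
#'   insulator_params(3.9, d_nm = 35),
#'   A_cm2 = 0.5,
#'   interface_potentials(phi_0_mV = -10))
#' @export
device_params <- function(semiconductor, insulator, A_cm2, interface,
                          constants = physical_constants()) {
  stopifnot(inherits(semiconductor, "semiconductor_params"),
            inherits(insulator, "insulator_params"),
            inherits(interface, "interface_potentials"),
            is.numeric(A_cm2), length(A_cm2) == 1)
  if (A_cm2 <= 0) stop("device area must be positive")
  structure(
    list(semiconductor = semiconductor,
         insulator = insulator,
         A = A_cm2 * 1e-4,          # m^2
         interface = interface,
         constants = constants,
         io = list(A_cm2 = A_cm2)),
    class = "eiscap_device")
}

#' @export
print.eiscap_device <- function(x, ...) {
  cat("EISCAP device\n")
  cat(sprintf("  semiconductor: eps_r = %g, N_a = %g cm^-3, n_i = %g cm^-3, T = %g K\n",
              x$semiconductor$eps_r, x$semiconductor$io$N_a_per_cm3,
              x$semiconductor$io$n_i_per_cm3, x$semiconductor$T))
  cat(sprintf("  insulator:     eps_r = %g, d = %g nm\n",
              x$insulator$eps_r, x$insulator$io$d_nm))
  cat(sprintf("  area:          %g cm^2\n", x$io$A_cm2))
  cat(sprintf("  potentials:    V_ip = %g V, phi_0 = %g mV\n",
              x$interface$V_ip, x$interface$io$phi_0_mV))
  cat(sprintf("  derived:       C_i0 = %.4g F/m^2, w_m = %.4g nm, C_acc = %.4g nF, C_inv = %.4g nF\n",
              insulator_capacitance_per_area(x$insulator, x$constants),
              max_depletion_width(x$semiconductor, x$constants) * 1e9,
              ceq_accumulation(x) * 1e9, ceq_inversion(x) * 1e9))
  invisible(x)
}

#' Insulator capacitance per unit area
#'
#' `C_i0 = eps_0 * eps_ir / d_i`, the series ceiling of every sub-region's
#' capacitance and the accumulation plateau per unit area.
#'
#' @param insulator an [insulator_params()] object.
#' @param constants physical constants (only `eps0` is used).
#' @return Capacitance per area in F/m^2.
#' @examples
#' insulator_capacitance_per_area(insulator_params(3.9, 35)) # ~9.866e-4
#' @export
insulator_capacitance_per_area <- function(insulator,
                                           constants = physical_constants()) {
  stopifnot(inherits(insulator, "insulator_params"))
  constants$eps0 * insulator$eps_r / insulator$d
}

#' Maximum depletion width
#'
#' Width the space-charge region saturates at under the high-frequency
#' strong-inversion assumption:
#' `w_m = sqrt(4 eps_s k T ln(N_a/n_i) / (q^2 N_a))`.
#'
#' @param semiconductor a [semiconductor_params()] object.
#' @param constants physical constants.
#' @return Length in metres.
#' @examples
#' max_depletion_width(semiconductor_params(11.7, 2.76e15, 1.5e10)) # ~5.43e-7
#' @export
max_depletion_width <- function(semiconductor,
                                constants = physical_constants()) {
  stopifnot(inherits(semiconductor, "semiconductor_params"))
  eps_s <- constants$eps0 * semiconductor$eps_r
  with(constants,
       sqrt(4 * eps_s * k * semiconductor$T *
              log(semiconductor$N_a / semiconductor$n_i) /
              (q^2 * semiconductor$N_a)))
}

#' Lumped particle-independent gate potential
#'
#' Sums the gate-voltage offsets that the nanoparticle decoration cannot
#' change: reference-electrode potential, solvent surface-dipole potential,
#' semiconductor work function (entered as phi_s/q, subtracted) and the
#' oxide/interface-state charge term (Q_i+Q_ss)/C_i.
#'
#' @param E_ref_V reference-electrode potential relative to vacuum (V).
#' @param chi_sol_V solvent surface-dipole potential (V).
#' @param phi_s_over_q_V semiconductor electron work function divided by the
#'   elementary charge (V); enters with a minus sign.
#' @param Q_over_Ci_V fixed oxide and interface-state charge divided by the
#'   insulator capacitance (V).
#' @return The lumped potential `V_ip` in volts.
#' @examples
#' lumped_interface_voltage(0.2, 0.05, 0.15, -0.1) # 0
#' @export
lumped_interface_voltage <- function(E_ref_V, chi_sol_V, phi_s_over_q_V,
                                     Q_over_Ci_V) {
  E_ref_V + chi_sol_V - phi_s_over_q_V + Q_over_Ci_V
}

# -- internal derived scalars ------------------------------------------------

# all take an eiscap_device; kept internal so units stay SI end to end
.eps_s <- function(device) device$constants$eps0 * device$semiconductor$eps_r
.Ci0 <- function(device)
  insulator_capacitance_per_area(device$insulator, device$constants)
.wm <- function(device)
  max_depletion_width(device$semiconductor, device$constants)

#' Canonical p-Si/SiO2 test device
#'
#' Convenience constructor for the Al/p-Si/SiO2 EISCAP parameter set used
#' throughout the examples and tests: 35 nm thermal oxide (eps_r = 3.9) on
#' p-silicon (eps_r = 11.7, N_a = 2.76e15 cm^-3 as for a 5 ohm-cm wafer,
#' n_i = 1.5e10 cm^-3) at 300 K, 0.5 cm^2 contact area, V_ip = 0 and a bare
#' surface potential of -10 mV.
#'
#' @param phi_0_mV bare-region interfacial potential (mV).
#' @param V_ip_V lumped particle-independent potential (V).
#' @return An `eiscap_device`.
#' @examples
#' si_sio2_device()
#' @export
si_sio2_device <- function(phi_0_mV = -10, V_ip_V = 0) {
  device_params(
    semiconductor = semiconductor_params(11.7, N_a_per_cm3 = 2.76e15,
                                         n_i_per_cm3 = 1.5e10, T_K = 300),
    insulator = insulator_params(3.9, d_nm = 35),
    A_cm2 = 0.5,
    interface = interface_potentials(phi_0_mV = phi_0_mV, V_ip_V = V_ip_V))
}
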