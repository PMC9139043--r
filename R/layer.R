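#' Nanoparticle decoration of the sensor surface
#'
#' Describes a layer of charged, ligand-stabilized nanoparticles adsorbed on
#' the gate insulator. The layer is characterized by its fractional surface
#' coverage `n` (projected hard-disk area fraction) and by the interfacial
#' potential change `delta_phi` the particle charge induces in the covered
#' region. `delta_phi` is either supplied directly (the usual case, since the
#' local double-layer capacitance is rarely known) or derived from particle
#' density, per-particle effective charge and double-layer capacitance via
#' [delta_phi_from_charge()]; exactly one of the two routes must be given.
#'
#' Coverage may likewise be given directly or derived from `density_per_cm2`
#' and `diameter_nm` via [coverage_from_density()].
#'
#' @param coverage fractional surface coverage `n` in `[0, 1)`; `n = 1` is
#'   accepted only as an analytic limit (single fully gated region).
#' @param delta_phi_mV interfacial potential change of the covered region
#'   (millivolts, signed: positive for positively charged particles).
#' @param density_per_cm2 particle surface density (cm^-2).
#' @param diameter_nm particle core diameter (nm); required when coverage is
#'   to be derived from density.
#' @param Q_NP_C effective charge per particle (coulombs, signed).
#' @param C_d_F_m2 double-layer capacitance per area in the covered region
#'   (F/m^2); required with `Q_NP_C`.
#' @param charge_sign optional +1/-1 overriding the sign taken from
#'   `delta_phi_mV` or `Q_NP_C`; the magnitude of `delta_phi` is kept and
#'   the sign applied.
#' @return An object of class `nanoparticle_layer` with SI fields `n`,
#'   `delta_phi` (V), `charge_sign`, and optionally `density` (m^-2),
#'   `diameter` (m), `Q_NP` (C), `C_d` (F/m^2).
#' @examples
#' nanoparticle_layer(coverage = 0.25, delta_phi_mV = 40)
#' nanoparticle_layer(density_per_cm2 = 6.17e10, diameter_nm = 28,
#'                    Q_NP_C = 1.6e-19, C_d_F_m2 = 0.1)
#' @export
nanoparticle_layer <- function(coverage = NULL, delta_phi_mV = NULL,
                               density_per_cm2 = NULL, diameter_nm = NULL,
                               Q_NP_C = NULL, C_d_F_m2 = NULL,
                               charge_sign = NULL) {
  have_direct <- !is.null(delta_phi_mV)
  have_charge <- !is.null(Q_NP_C) || !is.null(C_d_F_m2)
  if (have_direct && have_charge)
    stop("give either delta_phi_mV or (density_per_cm2, Q_NP_C, C_d_F_m2), not both")
  if (!have_direct && !have_charge)
    stop("delta_phi is undetermined: give delta_phi_mV or (density_per_cm2, Q_NP_C, C_d_F_m2)")

  density <- if (!is.null(density_per_cm2)) {
    stopifnot(is.numeric(density_per_cm2), density_per_cm2 >= 0)
    density_per_cm2 * 1e4            # m^-2
  }
  diameter <- if (!is.null(diameter_nm)) {
    stopifnot(is.numeric(diameter_nm), diameter_nm > 0)
    diameter_nm * 1e-9               # m
  }

  if (have_charge) {
    if (is.null(density) || is.null(Q_NP_C) || is.null(C_d_F_m2))
      stop("the charge route needs density_per_cm2, Q_NP_C and C_d_F_m2")
    delta_phi <- delta_phi_from_charge(density_per_cm2, Q_NP_C, C_d_F_m2)
  } else {
    stopifnot(is.numeric(delta_phi_mV), length(delta_phi_mV) == 1)
    delta_phi <- delta_phi_mV * 1e-3 # V
  }

  if (is.null(coverage)) {
    if (is.null(density) || is.null(diameter))
      stop("coverage is undetermined: give coverage or (density_per_cm2, diameter_nm)")
    coverage <- coverage_from_density(density_per_cm2, diameter_nm)
  }
  stopifnot(is.numeric(coverage), length(coverage) == 1)
  if (coverage < 0 || coverage > 1)
    stop("coverage must lie in [0, 1]")

  sgn <- if (!is.null(charge_sign)) {
    if (!charge_sign %in% c(-1, 1)) stop("charge_sign must be +1 or -1")
    charge_sign
  } else if (delta_phi != 0) sign(delta_phi) else 1
  delta_phi <- sgn * abs(delta_phi)

  structure(
    list(n = coverage, delta_phi = delta_phi, charge_sign = sgn,
         density = density, diameter = diameter,
         Q_NP = Q_NP_C, C_d = C_d_F_m2,
         io = list(delta_phi_mV = delta_phi * 1e3,
                   density_per_cm2 = density_per_cm2,
                   diameter_nm = diameter_nm)),
    class = "nanoparticle_layer")
}

#' @export
print.nanoparticle_layer <- function(x, ...) {
  cat(sprintf("Nanoparticle layer: n = %g, delta_phi = %g mV (sign %+d)\n",
              x$n, x$delta_phi * 1e3, x$charge_sign))
  if (!is.null(x$density))
    cat(sprintf("  density = %g cm^-2, diameter = %g nm\n",
                x$density * 1e-4, x$diameter * 1e9))
  invisible(x)
}

#' Bare (particle-free) layer
#'
#' @return A `nanoparticle_layer` with zero coverage and zero potential
#'   change; simulating with it reproduces the unmodified device.
#' @export
bare_layer <- function() nanoparticle_layer(coverage = 0, delta_phi_mV = 0)

#' Interfacial potential change induced by the particle charge
#'
#' First-order relation between the adsorbed charge sheet and the potential
#' it imposes at the insulator-electrolyte interface:
#' `delta_phi = N_NP * Q_NP / C_d`. `Q_NP` is the effective (counterion
#' screened) charge per particle, so the result already folds in the ionic
#' strength of the measurement buffer.
#'
#' @param density_per_cm2 particle surface density (cm^-2).
#' @param Q_NP_C effective charge per particle (coulombs, signed).
#' @param C_d_F_m2 double-layer capacitance per area (F/m^2), > 0.
#' @return Potential change in volts; sign follows `Q_NP_C`.
#' @examples
#' delta_phi_from_charge(6.17e10, 1.6e-19, 0.1) # ~9.87e-4 V
#' @export
delta_phi_from_charge <- function(density_per_cm2, Q_NP_C, C_d_F_m2) {
  stopifnot(is.numeric(density_per_cm2), is.numeric(Q_NP_C),
            is.numeric(C_d_F_m2))
  if (any(C_d_F_m2 <= 0)) stop("double-layer capacitance C_d must be positive")
  if (any(density_per_cm2 < 0)) stop("particle density must be non-negative")
  (density_per_cm2 * 1e4) * Q_NP_C / C_d_F_m2
}

# 2-D random-sequential-adsorption jamming limit for congruent hard disks;
# randomly adsorbed layers cannot exceed it, so higher values are suspect
.rsa_jamming_limit <- 0.547

#' Convert particle density to projected-disk coverage
#'
#' `n = N_NP * pi * d^2 / 4`, treating every particle as a hard disk of the
#' mean core diameter.
#'
#' @param density_per_cm2 particle surface density (cm^-2).
#' @param diameter_nm particle core diameter (nm).
#' @return Fractional coverage. Warns (does not fail) when the result
#'   reaches the 2-D random-sequential-adsorption jamming limit 0.547,
#'   which randomly adsorbed monodisperse disks cannot exceed.
#' @examples
#' coverage_from_density(6.17e10, 28) # ~0.380
#' @export
coverage_from_density <- function(density_per_cm2, diameter_nm) {
  stopifnot(is.numeric(density_per_cm2), is.numeric(diameter_nm))
  if (any(density_per_cm2 < 0)) stop("particle density must be non-negative")
  if (any(diameter_nm <= 0)) stop("particle diameter must be positive")
  n <- (density_per_cm2 * 1e4) * pi * (diameter_nm * 1e-9)^2 / 4
  if (any(n >= .rsa_jamming_limit))
    warning(sprintf(
      "coverage %.3g reaches the 2-D RSA jamming limit (%.3f); implausible for randomly adsorbed disks",
      max(n), .rsa_jamming_limit))
  n
}

#' Convert coverage to particle density
#'
#' Exact inverse of [coverage_from_density()].
#'
#' @param coverage fractional coverage in `[0, 1)`.
#' @param diameter_nm particle core diameter (nm).
#' @return Particle density in cm^-2.
#' @examples
#' density_from_coverage(0.36, 28) # ~5.85e10
#' @export
density_from_coverage <- function(coverage, diameter_nm) {
  stopifnot(is.numeric(coverage), is.numeric(diameter_nm))
  if (any(coverage < 0) || any(coverage >= 1))
    stop("coverage must lie in [0, 1)")
  if (any(diameter_nm <= 0)) stop("particle diameter must be positive")
  coverage / (pi * (diameter_nm * 1e-9)^2 / 4) * 1e-4
}
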