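# Two-region depletion-approximation C-V model.
#
# Each sub-region (particle-covered, particle-free) is a gate insulator in
# series with the space-charge layer underneath it, weighted by its area
# fraction; the device capacitance is the parallel sum of the two. The
# per-area series capacitance in depletion is 1/S(V_eff) with
#   S(x) = sqrt(1/C_i0^2 + 2 x / (q eps_s N_a)),
# where x is the gate voltage in excess of that sub-region's flat-band
# voltage. S is the reciprocal of the insulator+depletion series
# capacitance, since sqrt(1/C_i0^2 + 2x/(q eps_s N_a)) = 1/C_i0 + w(x)/eps_s.

# per-area reciprocal series capacitance at effective voltage x (>= 0)
.S <- function(x, device) {
  Ci0 <- .Ci0(device); eps_s <- .eps_s(device)
  q <- device$constants$q; Na <- device$semiconductor$N_a
  sqrt(1 / Ci0^2 + 2 * x / (q * eps_s * Na))
}

# effective voltage below which S(x) is not real: the residual's domain edge
.S_domain_min <- function(device) {
  -device$constants$q * .eps_s(device) * device$semiconductor$N_a /
    (2 * .Ci0(device)^2)
}

# per-area sub-region capacitance, clamped to the physical band
# [eps_s/w_m, C_i0]: the ceiling is the accumulation (insulator-only) value,
# the floor the high-frequency strong-inversion value. Clamping from below
# at the inversion floor keeps the assembled curve continuous and
# non-increasing and makes the inversion plateau equal eps_s A / w_m.
.subregion_cap_area <- function(V_eff, device) {
  Ci0 <- .Ci0(device)
  floor_c <- .eps_s(device) / .wm(device)
  out <- rep(Ci0, length(V_eff))
  dep <- V_eff > 0
  out[dep] <- pmax(1 / .S(V_eff[dep], device), floor_c)
  out
}

.subregion_regime <- function(V_eff, device) {
  floor_c <- .eps_s(device) / .wm(device)
  regime <- rep("depletion", length(V_eff))
  regime[V_eff <= 0] <- "accumulation"
  dep <- V_eff > 0
  regime[dep][1 / .S(V_eff[dep], device) <= floor_c] <- "inversion"
  regime
}

.phi_np <- function(device, layer) device$interface$phi_0 + layer$delta_phi

#' Depletion-layer width at a given effective voltage
#'
#' Space-charge width of a MOS-like stack at `V_eff = V_G - V_fb` (volts
#' above the applicable flat-band voltage):
#' `w = sqrt(eps_s^2/C_i0^2 + 2 eps_s V_eff / (q N_a)) - eps_s/C_i0`.
#' Zero at flat band and monotone increasing; the raw value is returned
#' without the strong-inversion cap (see [max_depletion_width()]).
#'
#' @param V_eff effective voltage(s), volts, >= 0.
#' @param device an `eiscap_device`.
#' @return Width(s) in metres.
#' @examples
#' depletion_width(0.04, si_sio2_device()) # ~6.76e-8 m
#' @export
depletion_width <- function(V_eff, device) {
  stopifnot(inherits(device, "eiscap_device"), is.numeric(V_eff))
  if (any(V_eff < 0))
    stop("V_eff must be non-negative (accumulation is handled by the caller)")
  eps_s <- .eps_s(device); Ci0 <- .Ci0(device)
  q <- device$constants$q; Na <- device$semiconductor$N_a
  sqrt(eps_s^2 / Ci0^2 + 2 * eps_s * V_eff / (q * Na)) - eps_s / Ci0
}

#' Flat-band voltages of the two sub-regions
#'
#' `V_fb = V_ip - phi_0` for the particle-free region and
#' `V_fbNP = V_ip - (phi_0 + delta_phi)` for the covered one; positively
#' charged particles (positive `delta_phi`) lower the covered region's
#' flat-band voltage, which is what shifts the C-V curve to more negative
#' gate voltages.
#'
#' @param device an `eiscap_device`.
#' @param layer a `nanoparticle_layer`.
#' @return Named list with `V_fb` and `V_fbNP` (volts).
#' @examples
#' flat_band_voltages(si_sio2_device(),
#'                    nanoparticle_layer(coverage = 0.25, delta_phi_mV = 40))
#' @export
flat_band_voltages <- function(device, layer) {
  stopifnot(inherits(device, "eiscap_device"),
            inherits(layer, "nanoparticle_layer"))
  V_ip <- device$interface$V_ip
  list(V_fb = V_ip - device$interface$phi_0,
       V_fbNP = V_ip - .phi_np(device, layer))
}

#' Accumulation-plateau capacitance
#'
#' In accumulation the semiconductor contributes no series capacitance and
#' the device reads the bare insulator: `C = eps_i A / d_i`, independent of
#' the particle coverage.
#'
#' @param device an `eiscap_device`.
#' @return Capacitance in farads.
#' @examples
#' ceq_accumulation(si_sio2_device()) * 1e9 # ~49.33 nF
#' @export
ceq_accumulation <- function(device) {
  stopifnot(inherits(device, "eiscap_device"))
  .Ci0(device) * device$A
}

#' Inversion-plateau capacitance
#'
#' High-frequency strong-inversion minimum `C = eps_s A / w_m`, again
#' coverage independent since both sub-regions saturate at the same maximum
#' depletion width.
#'
#' @param device an `eiscap_device`.
#' @return Capacitance in farads.
#' @examples
#' ceq_inversion(si_sio2_device()) * 1e9 # ~9.55 nF
#' @export
ceq_inversion <- function(device) {
  stopifnot(inherits(device, "eiscap_device"))
  .eps_s(device) * device$A / .wm(device)
}

#' Equivalent capacitance of the decorated device
#'
#' Area-weighted parallel sum of the two sub-region series capacitances:
#' `C = A n / S(V_G - V_ip + phi_0 + delta_phi) + A (1-n) / S(V_G - V_ip + phi_0)`.
#' Each sub-region term is clamped to its accumulation value below its
#' flat-band voltage and to its strong-inversion floor at high voltage, so
#' the function is total, continuous and non-increasing in `V_G`.
#'
#' @param V_G gate voltage(s), volts; vectorized.
#' @param device an `eiscap_device`.
#' @param layer a `nanoparticle_layer`.
#' @return Capacitance(s) in farads.
#' @examples
#' ceq_depletion(0.05, si_sio2_device(), bare_layer()) * 1e9 # ~30 nF
#' @export
ceq_depletion <- function(V_G, device, layer) {
  stopifnot(inherits(device, "eiscap_device"),
            inherits(layer, "nanoparticle_layer"), is.numeric(V_G))
  V_ip <- device$interface$V_ip
  x_np <- V_G - V_ip + .phi_np(device, layer)
  x_0 <- V_G - V_ip + device$interface$phi_0
  device$A * (layer$n * .subregion_cap_area(x_np, device) +
                (1 - layer$n) * .subregion_cap_area(x_0, device))
}

#' Equivalent capacitance via explicit series composition
#'
#' Cross-check form of [ceq_depletion()]: builds the four branch
#' capacitances (insulator and space charge of each sub-region) explicitly
#' and combines them as `C_iNP C_sNP/(C_iNP + C_sNP) + C_i C_s/(C_i + C_s)`.
#' Only defined where both sub-regions are strictly in depletion (positive
#' effective voltage, width below the strong-inversion cap); agrees with the
#' closed form to floating-point precision there.
#'
#' @inheritParams ceq_depletion
#' @return Capacitance(s) in farads; `NA` outside the joint depletion window.
#' @export
ceq_depletion_series <- function(V_G, device, layer) {
  stopifnot(inherits(device, "eiscap_device"),
            inherits(layer, "nanoparticle_layer"), is.numeric(V_G))
  V_ip <- device$interface$V_ip
  eps_i <- device$constants$eps0 * device$insulator$eps_r
  eps_s <- .eps_s(device)
  A <- device$A; d_i <- device$insulator$d; n <- layer$n

  series_term <- function(frac, x) {
    in_dep <- .subregion_regime(x, device) == "depletion"
    w <- ifelse(in_dep, depletion_width(pmax(x, 0), device), NA_real_)
    Ci <- eps_i * A * frac / d_i
    Cs <- eps_s * A * frac / w
    ifelse(frac == 0, 0, Ci * Cs / (Ci + Cs))
  }
  series_term(n, V_G - V_ip + .phi_np(device, layer)) +
    series_term(1 - n, V_G - V_ip + device$interface$phi_0)
}

#' Simulate a full C-V curve
#'
#' Evaluates the two-region model on a gate-voltage grid, labelling every
#' point with the regime of the device: `accumulation`, `depletion` or
#' `inversion` when both sub-regions agree, `mixed` where they differ (the
#' covered region enters each regime before the bare one when the particles
#' are positively charged).
#'
#' @param device an `eiscap_device`.
#' @param layer a `nanoparticle_layer`; defaults to the bare surface.
#' @param V_min,V_max grid limits (volts).
#' @param n_points number of grid points (>= 2); the default gives 1 mV
#'   spacing so linear interpolation error in readouts is far below 1 mV.
#' @return An object of class `eiscap_cv`: list with numeric vectors
#'   `V_G` (V), `C_eq` (F), character `region`, and the `device` and `layer`
#'   used. `as.data.frame()` yields the three columns.
#' @examples
#' cv <- simulate_cv(si_sio2_device(),
#'                   nanoparticle_layer(coverage = 0.5, delta_phi_mV = 40))
#' head(as.data.frame(cv))
#' @export
simulate_cv <- function(device, layer = bare_layer(),
                        V_min = -0.5, V_max = 1.5,
                        n_points = round((V_max - V_min) / 1e-3) + 1) {
  stopifnot(inherits(device, "eiscap_device"),
            inherits(layer, "nanoparticle_layer"))
  if (!(V_min < V_max)) stop("V_min must be below V_max")
  if (n_points < 2) stop("n_points must be at least 2")
  V_G <- seq(V_min, V_max, length.out = n_points)
  C_eq <- ceq_depletion(V_G, device, layer)

  V_ip <- device$interface$V_ip
  reg_np <- .subregion_regime(V_G - V_ip + .phi_np(device, layer), device)
  reg_0 <- .subregion_regime(V_G - V_ip + device$interface$phi_0, device)
  region <- if (layer$n == 0) reg_0
  else if (layer$n == 1) reg_np
  else ifelse(reg_np == reg_0, reg_0, "mixed")
  structure(list(V_G = V_G, C_eq = C_eq, region = region,
                 device = device, layer = layer),
            class = "eiscap_cv")
}

#' @export
as.data.frame.eiscap_cv <- function(x, ...) {
  data.frame(V_G = x$V_G, C_eq = x$C_eq, region = x$region)
}

#' @export
print.eiscap_cv <- function(x, ...) {
  cat(sprintf(
    "C-V curve: %d points on [%g, %g] V, C in [%.4g, %.4g] nF (n = %g, delta_phi = %g mV)\n",
    length(x$V_G), min(x$V_G), max(x$V_G),
    min(x$C_eq) * 1e9, max(x$C_eq) * 1e9, x$layer$n,
    x$layer$delta_phi * 1e3))
  invisible(x)
}

#' @param x an `eiscap_cv` object.
#' @param smooth_mV optional cosine-ramp smoothing window (mV) applied to
#'   the accumulation-depletion transition for display only; the model
#'   itself is piecewise (hard clamp) and all numeric readouts use the
#'   unsmoothed curve.
#' @param ... passed to [graphics::plot()].
#' @rdname simulate_cv
#' @export
plot.eiscap_cv <- function(x, smooth_mV = 0, ...) {
  C <- x$C_eq
  if (smooth_mV > 0) {
    # display-only cosine taper across the flat-band corner
    fb <- flat_band_voltages(x$device, x$layer)
    for (Vfb in unique(c(fb$V_fb, fb$V_fbNP))) {
      hw <- smooth_mV * 1e-3 / 2
      idx <- which(abs(x$V_G - Vfb) <= hw)
      if (length(idx) > 2) {
        lo <- min(idx) - 1; hi <- max(idx) + 1
        if (lo >= 1 && hi <= length(C)) {
          t <- (x$V_G[idx] - x$V_G[lo]) / (x$V_G[hi] - x$V_G[lo])
          C[idx] <- C[lo] + (C[hi] - C[lo]) * (1 - cos(pi * t)) / 2
        }
      }
    }
  }
  graphics::plot(x$V_G * 1e3, C * 1e9, type = "l",
                 xlab = "Gate voltage (mV)", ylab = "Capacitance (nF)", ...)
  invisible(x)
}

#' Voltage shift between two C-V curves at constant capacitance
#'
#' Reads each curve at the reference capacitance on its strictly decreasing
#' depletion branch (linear interpolation between grid points) and returns
#' `V(curve_b) - V(curve_a)`. This is the constant-capacitance readout of a
#' curve shift, e.g. bare device versus decorated device.
#'
#' @param curve_a,curve_b `eiscap_cv` objects on any grids.
#' @param C_ref reference capacitance (farads), strictly inside the
#'   depletion span of both curves.
#' @return Voltage shift in volts.
#' @export
cv_shift_at_capacitance <- function(curve_a, curve_b, C_ref) {
  .voltage_at_capacitance(curve_b, C_ref) -
    .voltage_at_capacitance(curve_a, C_ref)
}

.voltage_at_capacitance <- function(curve, C_ref) {
  stopifnot(inherits(curve, "eiscap_cv"), is.numeric(C_ref),
            length(C_ref) == 1)
  C <- curve$C_eq; V <- curve$V_G
  if (C_ref >= max(C) || C_ref <= min(C))
    stop(sprintf(
      "C_ref = %.4g nF is outside the curve's depletion span (%.4g, %.4g) nF",
      C_ref * 1e9, min(C) * 1e9, max(C) * 1e9))
  # C is non-increasing in V: locate the bracketing pair with C changing
  i <- which(C[-length(C)] > C_ref & C[-1] <= C_ref)
  if (length(i) == 0)
    stop("C_ref does not cross the curve's decreasing branch")
  i <- i[1]
  V[i] + (C[i] - C_ref) / (C[i] - C[i + 1]) * (V[i + 1] - V[i])
}

#' Capacitance change between two C-V curves at constant gate voltage
#'
#' `C(curve_b, V_ref) - C(curve_a, V_ref)` with linear interpolation; the
#' constant-voltage readout of a curve shift. For a p-type device decorated
#' with positively charged particles the change is negative in depletion and
#' its magnitude grows with coverage.
#'
#' @param curve_a,curve_b `eiscap_cv` objects.
#' @param V_ref gate voltage (volts) inside both grids.
#' @return Capacitance difference in farads.
#' @export
capacitance_change_at_voltage <- function(curve_a, curve_b, V_ref) {
  .capacitance_at_voltage(curve_b, V_ref) -
    .capacitance_at_voltage(curve_a, V_ref)
}

.capacitance_at_voltage <- function(curve, V_ref) {
  stopifnot(inherits(curve, "eiscap_cv"), is.numeric(V_ref),
            length(V_ref) == 1)
  if (V_ref < min(curve$V_G) || V_ref > max(curve$V_G))
    stop(sprintf("V_ref = %g V is outside the curve grid [%g, %g] V",
                 V_ref, min(curve$V_G), max(curve$V_G)))
  stats::approx(curve$V_G, curve$C_eq, xout = V_ref)$y
}

#' Write / read a C-V curve as CSV
#'
#' Columns `V_G_mV, C_eq_nF, region` (voltages to 0.001 mV, capacitances to
#' 0.001 nF) preceded by `#` comment lines carrying the full parameter set.
#'
#' @param curve an `eiscap_cv`.
#' @param path output file.
#' @return `path` invisibly; `read_cv_csv` returns a data.frame.
#' @export
write_cv_csv <- function(curve, path) {
  stopifnot(inherits(curve, "eiscap_cv"))
  dev <- curve$device; lay <- curve$layer
  hdr <- c(
    sprintf("# eiscap C-V curve"),
    sprintf("# eps_ir=%g d_i_nm=%g eps_sr=%g N_a_per_cm3=%g n_i_per_cm3=%g T_K=%g A_cm2=%g",
            dev$insulator$eps_r, dev$insulator$io$d_nm,
            dev$semiconductor$eps_r, dev$semiconductor$io$N_a_per_cm3,
            dev$semiconductor$io$n_i_per_cm3, dev$semiconductor$T,
            dev$io$A_cm2),
    sprintf("# V_ip_V=%g phi_0_mV=%g coverage=%g delta_phi_mV=%g",
            dev$interface$V_ip, dev$interface$io$phi_0_mV,
            lay$n, lay$delta_phi * 1e3))
  body <- sprintf("%.3f,%.3f,%s", curve$V_G * 1e3, curve$C_eq * 1e9,
                  curve$region)
  writeLines(c(hdr, "V_G_mV,C_eq_nF,region", body), path)
  invisible(path)
}

#' @rdname write_cv_csv
#' @export
read_cv_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}
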