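# Constant-capacitance (ConCap) readout.
#
# In ConCap mode a feedback loop adjusts the gate voltage so the device
# stays at a fixed working capacitance chosen on the depletion branch. A
# charged particle layer re-gates the covered sub-region, and the feedback
# voltage moves to compensate; the recorded voltage change is the sensor
# signal. For partial coverage the signal is strictly smaller in magnitude
# than the interfacial potential change in the covered region.

#' Gate voltage of the bare device at a working capacitance
#'
#' Closed-form inversion of the bare-device depletion relation:
#' `V_G = V_ip - phi_0 + (q eps_s N_a / 2) ((A/C_work)^2 - 1/C_i0^2)`.
#'
#' @param C_work working capacitance (farads), strictly between the
#'   inversion and accumulation plateaus.
#' @param device an `eiscap_device`.
#' @return Gate voltage in volts.
#' @examples
#' baseline_gate_voltage(30e-9, si_sio2_device()) # ~0.050 V
#' @export
baseline_gate_voltage <- function(C_work, device) {
  stopifnot(inherits(device, "eiscap_device"), is.numeric(C_work),
            length(C_work) == 1)
  C_acc <- ceq_accumulation(device); C_inv <- ceq_inversion(device)
  if (C_work >= C_acc || C_work <= C_inv)
    stop(sprintf(
      "C_work = %.4g nF is outside the depletion range (%.4g, %.4g) nF",
      C_work * 1e9, C_inv * 1e9, C_acc * 1e9))
  q <- device$constants$q; Na <- device$semiconductor$N_a
  eps_s <- .eps_s(device); A <- device$A; Ci0 <- .Ci0(device)
  device$interface$V_ip - device$interface$phi_0 +
    (q * eps_s * Na / 2) * ((A / C_work)^2 - 1 / Ci0^2)
}

# per-area constant-capacitance residual: lhs(V) - C_work/A, strictly
# decreasing in V; the depletion (unclamped) form unless clamp = TRUE
.concap_residual <- function(V, C_work, device, layer, clamp = FALSE) {
  if (clamp) return(ceq_depletion(V, device, layer) / device$A -
                      C_work / device$A)
  V_ip <- device$interface$V_ip
  n <- layer$n
  lhs <- 0
  if (n > 0) lhs <- lhs + n / .S(V - V_ip + .phi_np(device, layer), device)
  if (n < 1) lhs <- lhs + (1 - n) / .S(V - V_ip + device$interface$phi_0,
                                       device)
  lhs - C_work / device$A
}

# lowest gate voltage at which the unclamped residual is real-valued
.concap_domain_min <- function(device, layer) {
  V_ip <- device$interface$V_ip
  xmin <- .S_domain_min(device)
  lo <- -Inf
  if (layer$n > 0) lo <- max(lo, xmin + V_ip - .phi_np(device, layer))
  if (layer$n < 1) lo <- max(lo, xmin + V_ip - device$interface$phi_0)
  lo
}

#' Solve the constant-capacitance condition for the decorated device
#'
#' Finds the gate voltage `V_G_NP` at which the particle-decorated device
#' presents the same working capacitance as the bare device, by bracketed
#' root finding on the strictly monotone per-area capacitance balance
#' (the depletion relation of both sub-regions summed with their area
#' weights). The ConCap signal is `delta_V = V_G_NP - V_G_baseline`; its
#' sign is opposite to the particle charge and its magnitude is strictly
#' below `|delta_phi|` for partial coverage.
#'
#' The initial bracket spans `V_G_baseline +/- (2 |delta_phi| + 0.5 V)`,
#' truncated below to the domain where the depletion relation is real, and
#' is widened geometrically (at most 5 times) if it fails to straddle the
#' root. If at the solution either sub-region has left depletion (effective
#' voltage below zero or width beyond the strong-inversion cap) the
#' condition is re-solved with the regime-clamped capacitance and the
#' result flagged `clamped = TRUE`.
#'
#' @param C_work working capacitance (farads), on the bare device's
#'   depletion branch.
#' @param device an `eiscap_device`.
#' @param layer a `nanoparticle_layer`.
#' @param tol absolute voltage tolerance of the root (volts).
#' @return An object of class `concap_result`: list with `C_work`,
#'   `V_G_baseline`, `V_G_NP`, `delta_V` (all volts/farads, SI),
#'   `iterations`, `residual` (farads at the solution), `clamped`, and
#'   `regimes` (regime of the covered and free sub-regions at the solved
#'   voltage).
#' @examples
#' solve_concap_voltage(30e-9, si_sio2_device(),
#'                      nanoparticle_layer(coverage = 0.25, delta_phi_mV = 40))
#' @export
solve_concap_voltage <- function(C_work, device, layer, tol = 1e-10) {
  stopifnot(inherits(device, "eiscap_device"),
            inherits(layer, "nanoparticle_layer"))
  V_base <- baseline_gate_voltage(C_work, device)

  dom_lo <- .concap_domain_min(device, layer)
  half <- 2 * abs(layer$delta_phi) + 0.5
  lo <- max(V_base - half, dom_lo + 1e-12)
  hi <- V_base + half

  f <- function(V) .concap_residual(V, C_work, device, layer)
  flo <- f(lo); fhi <- f(hi)
  expansions <- 0L
  while (flo * fhi > 0 && expansions < 5L) {
    half <- half * 2
    lo <- max(V_base - half, dom_lo + 1e-12)
    hi <- V_base + half
    flo <- f(lo); fhi <- f(hi)
    expansions <- expansions + 1L
  }
  if (flo * fhi > 0)
    stop(sprintf(
      "no sign change in [%.4g, %.4g] V after %d bracket expansions (C_work = %.4g nF, n = %g, delta_phi = %g mV)",
      lo, hi, expansions, C_work * 1e9, layer$n, layer$delta_phi * 1e3))

  root <- stats::uniroot(f, c(lo, hi), f.lower = flo, f.upper = fhi,
                         tol = tol, maxiter = 200)
  V_np <- root$root
  clamped <- FALSE

  # regime guard: the depletion-only balance assumes both sub-regions
  # depleted; re-solve with the clamped capacitance if one has left
  V_ip <- device$interface$V_ip
  regimes_at <- function(V) c(
    covered = if (layer$n > 0)
      .subregion_regime(V - V_ip + .phi_np(device, layer), device)
    else NA_character_,
    free = if (layer$n < 1)
      .subregion_regime(V - V_ip + device$interface$phi_0, device)
    else NA_character_)
  regimes <- regimes_at(V_np)
  out_of_regime <- any(regimes != "depletion", na.rm = TRUE)
  if (out_of_regime) {
    g <- function(V) .concap_residual(V, C_work, device, layer, clamp = TRUE)
    glo <- g(V_base - half); ghi <- g(V_base + half)
    if (glo * ghi > 0)
      stop("clamped re-solve failed to bracket the working capacitance")
    root <- stats::uniroot(g, c(V_base - half, V_base + half),
                           f.lower = glo, f.upper = ghi,
                           tol = tol, maxiter = 200)
    V_np <- root$root
    clamped <- TRUE
    regimes <- regimes_at(V_np)
  }

  structure(
    list(C_work = C_work,
         V_G_baseline = V_base,
         V_G_NP = V_np,
         delta_V = V_np - V_base,
         iterations = root$iter,
         residual = .concap_residual(V_np, C_work, device, layer,
                                     clamp = clamped) * device$A,
         clamped = clamped,
         regimes = regimes),
    class = "concap_result")
}

#' @export
print.concap_result <- function(x, ...) {
  cat(sprintf(
    "ConCap: C_work = %.4g nF, V_G = %.3f mV -> V_G_NP = %.3f mV, delta_V = %.3f mV%s\n",
    x$C_work * 1e9, x$V_G_baseline * 1e3, x$V_G_NP * 1e3, x$delta_V * 1e3,
    if (x$clamped) " (regime-clamped)" else ""))
  invisible(x)
}

#' ConCap signal versus particle coverage
#'
#' Solves the constant-capacitance condition for each coverage at a fixed
#' interfacial potential change, reproducing the signal-versus-coverage
#' characteristic of the decorated sensor.
#'
#' @param coverages numeric vector of fractional coverages.
#' @param C_work working capacitance (farads).
#' @param device an `eiscap_device`.
#' @param delta_phi_mV interfacial potential change of the covered region
#'   (mV).
#' @return A data.frame with columns `coverage`, `delta_V_mV`, `V_G_NP_mV`,
#'   `iterations`; rows in input order. The full `concap_result` objects
#'   are attached as attribute `"results"`.
#' @examples
#' concap_sweep(c(0.25, 0.5, 0.75, 0.9), 30e-9, si_sio2_device(), 40)
#' @export
concap_sweep <- function(coverages, C_work, device, delta_phi_mV) {
  stopifnot(is.numeric(coverages))
  results <- lapply(coverages, function(n) {
    tryCatch(
      solve_concap_voltage(C_work, device,
                           nanoparticle_layer(coverage = n,
                                              delta_phi_mV = delta_phi_mV)),
      error = function(e)
        stop(sprintf("ConCap solve failed at coverage %g: %s", n,
                     conditionMessage(e)), call. = FALSE))
  })
  out <- data.frame(
    coverage = coverages,
    delta_V_mV = vapply(results, function(r) r$delta_V * 1e3, numeric(1)),
    V_G_NP_mV = vapply(results, function(r) r$V_G_NP * 1e3, numeric(1)),
    iterations = vapply(results, function(r) as.numeric(r$iterations),
                        numeric(1)))
  attr(out, "results") <- results
  out
}

#' Step protocol for a ConCap time series
#'
#' An ordered sequence of exposure segments, each holding one particle
#' layer for a given duration — the in-silico analogue of incubating the
#' sensor stepwise to higher coverages and recording the stabilized ConCap
#' plateau after each step.
#'
#' @param durations_s numeric vector of segment durations (seconds, > 0).
#' @param layers list of `nanoparticle_layer` objects, one per segment;
#'   alternatively give `coverages` and a common `delta_phi_mV`.
#' @param coverages,delta_phi_mV shortcut for building the layers.
#' @param sampling_interval_s sampling interval of the synthesized trace.
#' @return An object of class `step_protocol`.
#' @examples
#' step_protocol(c(60, 60, 60), coverages = c(0, 0.12, 0.36),
#'               delta_phi_mV = 40)
#' @export
step_protocol <- function(durations_s, layers = NULL, coverages = NULL,
                          delta_phi_mV = NULL, sampling_interval_s = 1) {
  stopifnot(is.numeric(durations_s), all(durations_s > 0),
            is.numeric(sampling_interval_s), sampling_interval_s > 0)
  if (is.null(layers)) {
    if (is.null(coverages) || is.null(delta_phi_mV))
      stop("give layers, or coverages plus delta_phi_mV")
    layers <- lapply(coverages, function(n)
      nanoparticle_layer(coverage = n, delta_phi_mV = delta_phi_mV))
  }
  if (length(layers) != length(durations_s))
    stop("one layer per duration required")
  stopifnot(all(vapply(layers, inherits, logical(1), "nanoparticle_layer")))
  structure(list(durations_s = durations_s, layers = layers,
                 sampling_interval_s = sampling_interval_s),
            class = "step_protocol")
}

#' Simulate a ConCap time series over a step protocol
#'
#' Piecewise-constant idealized trace: each segment sits at the ConCap
#' signal level of its layer (no adsorption kinetics, no drift — levels are
#' the stabilized plateaus).
#'
#' @param protocol a [step_protocol()].
#' @param C_work working capacitance (farads).
#' @param device an `eiscap_device`.
#' @return data.frame with columns `time_s`, `delta_V_mV`, `coverage`.
#' @export
simulate_concap_timeseries <- function(protocol, C_work, device) {
  stopifnot(inherits(protocol, "step_protocol"))
  levels_mV <- vapply(protocol$layers, function(lay)
    solve_concap_voltage(C_work, device, lay)$delta_V * 1e3, numeric(1))
  ends <- cumsum(protocol$durations_s)
  times <- seq(0, ends[length(ends)], by = protocol$sampling_interval_s)
  seg <- findInterval(times, ends, left.open = TRUE) + 1L
  seg[seg > length(levels_mV)] <- length(levels_mV)
  data.frame(time_s = times,
             delta_V_mV = levels_mV[seg],
             coverage = vapply(protocol$layers, function(l) l$n,
                               numeric(1))[seg])
}

#' Infer the interfacial potential change from an observed ConCap shift
#'
#' Model-based inversion of the forward ConCap solver: finds the
#' `delta_phi` whose predicted signal at the given coverage equals the
#' observed shift. Because partial coverage attenuates the signal, the
#' recovered `|delta_phi|` always exceeds `|observed_delta_V|` (they agree
#' at full coverage).
#'
#' @param coverage fractional coverage, in (0, 1].
#' @param observed_delta_V observed ConCap signal change (volts, signed).
#' @param C_work working capacitance (farads).
#' @param device an `eiscap_device`.
#' @param search_limit_mV half-width of the search interval for
#'   `delta_phi` (mV).
#' @return The inferred `delta_phi` in volts (opposite sign to the
#'   observed shift). Errors if no `delta_phi` within the search range
#'   reproduces the observation.
#' @examples
#' r <- solve_concap_voltage(30e-9, si_sio2_device(),
#'        nanoparticle_layer(coverage = 0.25, delta_phi_mV = 40))
#' estimate_delta_phi(0.25, r$delta_V, 30e-9, si_sio2_device()) # ~0.040 V
#' @export
estimate_delta_phi <- function(coverage, observed_delta_V, C_work, device,
                               search_limit_mV = 500) {
  stopifnot(is.numeric(coverage), length(coverage) == 1,
            is.numeric(observed_delta_V), length(observed_delta_V) == 1)
  if (coverage <= 0 || coverage > 1)
    stop("coverage must lie in (0, 1] for the inversion to be defined")
  if (observed_delta_V == 0) return(0)

  sgn <- -sign(observed_delta_V)  # recovered delta_phi opposes the shift
  solve_at <- function(dphi_V) {
    lay <- nanoparticle_layer(coverage = coverage,
                              delta_phi_mV = dphi_V * 1e3)
    solve_concap_voltage(C_work, device, lay)
  }
  fwd <- function(dphi_V) solve_at(dphi_V)$delta_V - observed_delta_V
  lo <- 0; hi <- sgn * search_limit_mV * 1e-3
  flo <- fwd(lo); fhi <- fwd(hi)
  if (flo * fhi > 0) {
    # a residual pinned at ~0 at the search limit means the forward signal
    # has saturated (covered region out of depletion): the observation sits
    # on the flat branch and delta_phi is not identifiable from it
    if (abs(fhi) < 1e-7)
      stop(sprintf(
        "delta_phi is not identifiable: the covered region leaves depletion at the working point and the signal saturates at %.3f mV",
        (fhi + observed_delta_V) * 1e3))
    stop(sprintf(
      "observed delta_V = %.3f mV is unattainable at coverage %g within |delta_phi| <= %g mV",
      observed_delta_V * 1e3, coverage, search_limit_mV))
  }
  root <- stats::uniroot(fwd, sort(c(lo, hi)), tol = 1e-10, maxiter = 200)
  dphi <- root$root
  chk <- solve_at(dphi)
  if (!is.na(chk$regimes["covered"]) && chk$regimes["covered"] != "depletion")
    stop(sprintf(
      "delta_phi is not identifiable: the covered region is in %s at the recovered solution",
      chk$regimes["covered"]))
  # forward consistency check
  resid <- chk$delta_V - observed_delta_V
  if (abs(resid) > 1e-5)
    stop(sprintf("inversion residual %.3g mV exceeds 0.01 mV", resid * 1e3))
  dphi
}
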