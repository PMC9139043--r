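dev <- ref_device()
C30 <- 30e-9

test_that("baseline gate voltage inverts the bare depletion relation", {
  expect_equal(baseline_gate_voltage(C30, dev), 0.05003714673,
               tolerance = 1e-9)
  # flat-band limit: C_work -> accumulation plateau gives V_fb
  C_near_acc <- ceq_accumulation(dev) * (1 - 1e-9)
  expect_equal(baseline_gate_voltage(C_near_acc, dev), 0.010,
               tolerance = 1e-6)
  # round-trip through the forward model
  for (C in c(12e-9, 30e-9, 45e-9)) {
    V <- baseline_gate_voltage(C, dev)
    expect_equal(ceq_depletion(V, dev, bare_layer()), C, tolerance = 1e-12)
  }
  expect_error(baseline_gate_voltage(60e-9, dev), "outside the depletion")
  expect_error(baseline_gate_voltage(5e-9, dev), "outside the depletion")
})

test_that("ConCap solve reduces to the baseline at zero coverage and to a
           rigid shift at full coverage", {
  r0 <- solve_concap_voltage(C30, dev, ref_layer(0, 40))
  expect_equal(r0$delta_V, 0, tolerance = 1e-9)
  r1 <- solve_concap_voltage(C30, dev, ref_layer(1, 40))
  expect_equal(r1$delta_V, -0.040, tolerance = 1e-10)
  expect_lt(abs(r1$residual), 1e-15 * dev$A / 1e-4)
})

test_that("ConCap signal opposes the particle charge and is bounded by
           delta_phi, strictly monotone in coverage", {
  covs <- seq(0.05, 0.95, length.out = 20)
  dV <- concap_sweep(covs, C30, dev, 40)$delta_V_mV
  expect_true(all(dV < 0))
  expect_true(all(abs(dV) < 40))
  expect_true(all(diff(dV) < 0))

  # negative particle charge mirrors the signal
  neg <- nanoparticle_layer(coverage = 0.5, delta_phi_mV = 40,
                            charge_sign = -1)
  expect_gt(solve_concap_voltage(C30, dev, neg)$delta_V, 0)
})

test_that("ConCap signal is monotone in delta_phi and area independent", {
  dphis <- seq(-100, 100, by = 25)
  dV <- vapply(dphis, function(p)
    solve_concap_voltage(C30, dev, ref_layer(0.5, p))$delta_V, numeric(1))
  expect_true(all(diff(dV) < 0))
  expect_equal(dV[dphis == 0], 0, tolerance = 1e-9)

  # per-area formulation: scaling A and C_work together changes nothing
  dev2 <- device_params(dev$semiconductor, dev$insulator, A_cm2 = 2,
                        dev$interface)
  r_small <- solve_concap_voltage(C30, dev, ref_layer(0.4, 40))
  r_big <- solve_concap_voltage(C30 * 4, dev2, ref_layer(0.4, 40))
  expect_equal(r_big$delta_V, r_small$delta_V, tolerance = 1e-9)
})

test_that("solver agrees with a dense-grid scan of the residual", {
  set.seed(101)
  for (k in 1:50) {
    dphi <- runif(1, -80, 80)
    n <- runif(1, 0.05, 0.95)
    # random but valid device
    # doping/thickness kept where the inversion plateau sits below the
    # accumulation plateau, as in any sensibly designed EISCAP
    d <- device_params(
      semiconductor_params(11.7, runif(1, 5e14, 1e16), 1.5e10),
      insulator_params(3.9, runif(1, 20, 60)),
      A_cm2 = 0.5,
      interface_potentials(phi_0_mV = runif(1, -30, 10)))
    C_work <- 0.5 * (ceq_accumulation(d) + ceq_inversion(d))
    res <- solve_concap_voltage(C_work, d, ref_layer(n, dphi))
    # brute force: densely sample the capacitance balance and take the
    # grid point with the smallest absolute residual
    span <- 2 * abs(dphi) * 1e-3 + 0.1
    Vs <- seq(res$V_G_NP - span, res$V_G_NP + span, length.out = 1e5)
    cap <- ceq_depletion(Vs, d, ref_layer(n, dphi))
    V_scan <- Vs[which.min(abs(cap - C_work))]
    expect_lt(abs(res$V_G_NP - V_scan), 2 * span / 1e5 * 2)
  }
})

test_that("coverage sweep keeps input order and propagates failures", {
  sw <- concap_sweep(c(0.9, 0.25), C30, dev, 40)
  expect_identical(sw$coverage, c(0.9, 0.25))
  expect_lt(sw$delta_V_mV[1], sw$delta_V_mV[2])
  empty <- concap_sweep(numeric(0), C30, dev, 40)
  expect_identical(nrow(empty), 0L)
  both <- concap_sweep(c(0, 1), C30, dev, 40)
  expect_equal(both$delta_V_mV, c(0, -40), tolerance = 1e-6)
  expect_error(concap_sweep(c(0.25, 2), C30, dev, 40), "coverage 2")
})

test_that("step-protocol time series is piecewise constant with the
           stepwise-coverage plateaus", {
  flat <- simulate_concap_timeseries(
    step_protocol(60, coverages = 0, delta_phi_mV = 40,
                  sampling_interval_s = 5), C30, dev)
  expect_true(all(abs(flat$delta_V_mV) < 1e-6))

  prot <- step_protocol(c(60, 60, 60, 60),
                        coverages = c(0, 0.12, 0.22, 0.36),
                        delta_phi_mV = 40, sampling_interval_s = 2)
  tr <- simulate_concap_timeseries(prot, C30, dev)
  levels <- unique(tr$delta_V_mV)
  expect_identical(length(levels), 4L)
  expect_true(all(diff(levels) < 0))
  # plateau levels equal the stationary solver results
  for (i in seq_along(levels)) {
    expect_equal(levels[i],
                 solve_concap_voltage(C30, dev, prot$layers[[i]])$delta_V * 1e3,
                 tolerance = 1e-9)
  }
  # repeating a segment reproduces its level exactly
  rep2 <- simulate_concap_timeseries(
    step_protocol(c(30, 30), coverages = c(0.12, 0.12), delta_phi_mV = 40),
    C30, dev)
  expect_identical(length(unique(rep2$delta_V_mV)), 1L)
})

test_that("estimate_delta_phi inverts the forward solver", {
  expect_identical(estimate_delta_phi(0.5, 0, C30, dev), 0)
  # full coverage identity
  expect_equal(estimate_delta_phi(1, -0.040, C30, dev), 0.040,
               tolerance = 1e-7)
  # parameter recovery across the (coverage, delta_phi) grid; where the
  # covered region saturates out of depletion the signal carries no
  # delta_phi information and the inverse must say so instead
  for (n in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    for (dphi_mV in c(-100, -50, -10, 10, 50, 100)) {
      fwd <- solve_concap_voltage(C30, dev, ref_layer(n, dphi_mV))
      if (fwd$regimes[["covered"]] != "depletion") {
        expect_error(estimate_delta_phi(n, fwd$delta_V, C30, dev),
                     "not identifiable")
      } else {
        est <- estimate_delta_phi(n, fwd$delta_V, C30, dev)
        expect_lt(abs(est * 1e3 - dphi_mV), 0.1)
      }
    }
  }
  expect_error(estimate_delta_phi(0, -0.01, C30, dev), "coverage")
  # a shift larger than any attainable signal at low coverage
  expect_error(estimate_delta_phi(0.05, -0.2, C30, dev, search_limit_mV = 300),
               "unattainable")
})

test_that("ConCap shift matches the C-V curve shift at the same working
           capacitance", {
  cv0 <- simulate_cv(dev, bare_layer(), -0.2, 0.8, n_points = 1001)
  for (n in c(0.25, 0.5, 0.9)) {
    cvn <- simulate_cv(dev, ref_layer(n, 40), -0.2, 0.8, n_points = 1001)
    shift <- cv_shift_at_capacitance(cv0, cvn, C30)
    solved <- solve_concap_voltage(C30, dev, ref_layer(n, 40))$delta_V
    expect_lt(abs(shift - solved), 1e-5)  # 0.01 mV interpolation error
  }
})
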