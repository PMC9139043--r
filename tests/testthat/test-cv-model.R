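dev <- ref_device()

test_that("depletion width is zero at flat band, monotone, and matches the
           charge-balance oracle", {
  expect_equal(depletion_width(0, dev), 0)
  expect_equal(depletion_width(0.04, dev), 6.760252152e-8, tolerance = 1e-9)
  expect_error(depletion_width(-0.01, dev), "non-negative")

  V <- seq(0, 2, length.out = 200)
  w <- depletion_width(V, dev)
  expect_true(all(diff(w) > 0))

  # independent oracle: solve the 1-D depletion charge balance
  # V_eff = q N_a w^2 / (2 eps_s) + q N_a w / C_i0 for w numerically
  q <- 1.6e-19; eps0 <- 8.854e-12; eps_s <- eps0 * 11.7
  Na <- 2.76e21; Ci0 <- eps0 * 3.9 / 35e-9
  for (Veff in c(0.005, 0.04, 0.2, 1.0)) {
    w_oracle <- uniroot(function(w)
      q * Na * w^2 / (2 * eps_s) + q * Na * w / Ci0 - Veff,
      c(0, 1e-5), tol = 1e-15)$root
    expect_lt(abs(depletion_width(Veff, dev) - w_oracle), 1e-10) # 0.1 nm
  }
})

test_that("flat-band voltages follow the interfacial potentials and charge sign", {
  fb <- flat_band_voltages(dev, ref_layer(0.25, 40))
  expect_equal(fb$V_fb, 0.010)
  expect_equal(fb$V_fbNP, -0.030)
  expect_lt(fb$V_fbNP, fb$V_fb)  # positive charge lowers the flat band

  fb0 <- flat_band_voltages(dev, ref_layer(0.25, 0))
  expect_equal(fb0$V_fbNP, fb0$V_fb)

  neg <- nanoparticle_layer(coverage = 0.25, delta_phi_mV = 40,
                            charge_sign = -1)
  fbn <- flat_band_voltages(dev, neg)
  expect_equal(fbn$V_fbNP, fbn$V_fb + 0.040)
})

test_that("accumulation plateau is the insulator capacitance, coverage-free", {
  expect_equal(ceq_accumulation(dev), 4.932942857e-8, tolerance = 1e-9)
  dev2 <- device_params(dev$semiconductor, dev$insulator, A_cm2 = 1,
                        dev$interface)
  expect_equal(ceq_accumulation(dev2), 2 * ceq_accumulation(dev))
})

test_that("inversion plateau equals eps_s A / w_m", {
  expect_equal(ceq_inversion(dev), 9.547233253e-9, tolerance = 1e-9)
  expect_equal(ceq_inversion(dev),
               8.854e-12 * 11.7 * dev$A /
                 max_depletion_width(dev$semiconductor))
})

test_that("equivalent depletion capacitance hits its anchors", {
  # bare device at the 50 mV working point reads ~30 nF
  expect_equal(ceq_depletion(0.05, dev, bare_layer()), 3.000877365e-8,
               tolerance = 1e-9)
  # at flat band the bare device reads the accumulation plateau
  expect_equal(ceq_depletion(0.010, dev, bare_layer()),
               ceq_accumulation(dev), tolerance = 1e-12)
  # partial coverage lies strictly between the 0 and 1 coverage curves
  V <- 0.1
  c0 <- ceq_depletion(V, dev, ref_layer(0, 40))
  c1 <- ceq_depletion(V, dev, ref_layer(1, 40))
  ch <- ceq_depletion(V, dev, ref_layer(0.5, 40))
  expect_true(ch < c0 && ch > c1)
})

test_that("closed form agrees with the explicit series composition", {
  set.seed(42)
  m <- 1000
  Vg <- runif(m, 0.05, 0.6)
  nn <- runif(m, 0.01, 0.99)
  dphi <- runif(m, 1, 60)
  checked <- 0L
  for (i in seq_len(m)) {
    lay <- ref_layer(nn[i], dphi[i])
    series <- ceq_depletion_series(Vg[i], dev, lay)
    if (is.na(series)) next  # a sub-region outside joint depletion
    closed <- ceq_depletion(Vg[i], dev, lay)
    expect_lt(abs(series - closed) / closed, 1e-12)
    checked <- checked + 1L
  }
  expect_gt(checked, 900)
})

test_that("assembled C-V curves are bounded, continuous and non-increasing", {
  for (lay in list(bare_layer(), ref_layer(0.5, 40), ref_layer(0.9, 40),
                   nanoparticle_layer(coverage = 0.5, delta_phi_mV = 40,
                                      charge_sign = -1))) {
    cv <- simulate_cv(dev, lay, -0.5, 1.5, n_points = 2001)
    expect_true(all(diff(cv$C_eq) <= 1e-18))
    expect_true(all(cv$C_eq <= ceq_accumulation(dev) + 1e-15))
    expect_true(all(cv$C_eq >= ceq_inversion(dev) - 1e-15))
    # continuity: the largest per-step change shrinks in proportion to the
    # grid spacing (a jump discontinuity would not)
    fine <- simulate_cv(dev, lay, -0.5, 1.5, n_points = 8001)
    expect_lt(max(abs(diff(fine$C_eq))),
              max(abs(diff(cv$C_eq))) / 4 * 1.5)
  }
})

test_that("bare-device plateaus match the closed-form limits", {
  cv <- simulate_cv(dev, bare_layer(), -0.5, 1.5, n_points = 2001)
  expect_equal(cv$C_eq[1], ceq_accumulation(dev), tolerance = 1e-12)
  expect_equal(cv$C_eq[length(cv$C_eq)], ceq_inversion(dev),
               tolerance = 1e-12)
  expect_identical(cv$region[1], "accumulation")
  expect_identical(cv$region[length(cv$region)], "inversion")
  expect_true("depletion" %in% cv$region)
})

test_that("zero coverage nullifies delta_phi and vice versa", {
  grid <- c(-0.2, 0, 0.05, 0.2, 0.8)
  for (dphi in c(0, 25, 80)) {
    expect_equal(ceq_depletion(grid, dev, ref_layer(0, dphi)),
                 ceq_depletion(grid, dev, bare_layer()), tolerance = 1e-15)
  }
  for (n in c(0.1, 0.5, 0.9)) {
    expect_equal(ceq_depletion(grid, dev, ref_layer(n, 0)),
                 ceq_depletion(grid, dev, bare_layer()), tolerance = 1e-15)
  }
})

test_that("full coverage shifts the curve rigidly by delta_phi", {
  cv0 <- simulate_cv(dev, bare_layer(), -0.2, 0.8, n_points = 1001)
  cv1 <- simulate_cv(dev, ref_layer(1, 40), -0.2, 0.8, n_points = 1001)
  for (C_ref in c(15e-9, 30e-9, 45e-9)) {
    expect_equal(cv_shift_at_capacitance(cv0, cv1, C_ref), -0.040,
                 tolerance = 1e-5)
  }
})

test_that("positive particle charge decreases capacitance, more so at higher
           coverage, and shifts are negative and monotone", {
  cv0 <- simulate_cv(dev, bare_layer(), -0.2, 0.8, n_points = 1001)
  covs <- c(0.25, 0.5, 0.75, 0.9)
  dC <- vapply(covs, function(n)
    capacitance_change_at_voltage(
      cv0, simulate_cv(dev, ref_layer(n, 40), -0.2, 0.8, n_points = 1001),
      0.05), numeric(1))
  expect_true(all(dC < 0))
  expect_true(all(diff(abs(dC)) > 0))

  dV <- vapply(covs, function(n)
    cv_shift_at_capacitance(
      cv0, simulate_cv(dev, ref_layer(n, 40), -0.2, 0.8, n_points = 1001),
      30e-9), numeric(1))
  expect_true(all(dV < 0))
  expect_true(all(diff(dV) < 0))  # more negative with coverage
})

test_that("curve readouts reject out-of-span references", {
  cv0 <- simulate_cv(dev, bare_layer(), -0.2, 0.8, n_points = 501)
  expect_equal(cv_shift_at_capacitance(cv0, cv0, 30e-9), 0)
  expect_equal(capacitance_change_at_voltage(cv0, cv0, 0.05), 0)
  expect_error(cv_shift_at_capacitance(cv0, cv0, 60e-9), "outside")
  expect_error(cv_shift_at_capacitance(cv0, cv0, 5e-9), "outside")
  expect_error(capacitance_change_at_voltage(cv0, cv0, 2), "outside")
})

test_that("simulate_cv validates its grid", {
  expect_error(simulate_cv(dev, bare_layer(), 0.5, -0.5), "V_min")
  expect_error(simulate_cv(dev, bare_layer(), -0.5, 0.5, n_points = 1),
               "n_points")
})

test_that("C-V curves round-trip through the CSV writer", {
  cv <- simulate_cv(dev, ref_layer(0.25, 40), -0.1, 0.3, n_points = 401)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cv_csv(cv, path)
  back <- read_cv_csv(path)
  expect_identical(nrow(back), length(cv$V_G))
  # stated CSV precision: 0.001 mV and 0.001 nF
  expect_lt(max(abs(back$V_G_mV - cv$V_G * 1e3)), 5e-4 + 1e-12)
  expect_lt(max(abs(back$C_eq_nF - cv$C_eq * 1e9)), 5e-4 + 1e-12)
  expect_identical(back$region, cv$region)
})
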