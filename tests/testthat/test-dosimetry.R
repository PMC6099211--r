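# Calibration models, dose reconstruction, uncertainty propagation.

test_that("film calibration fit recovers generating coefficients", {
  a <- 0.5676; b <- -440.7870
  x <- c(0.01, 0.02, 0.035, 0.05, 0.07, 0.1, 0.14)
  pairs <- data.frame(net_dR = x, kerma_mGy = a + b * x / log(x))
  fit <- fit_gaf_calibration(pairs, depth_cm = 0)
  expect_equal(fit$a, a, tolerance = 1e-6)
  expect_equal(fit$b, b, tolerance = 1e-6)
  # fitted curve reproduces the inputs within the reported residuals
  expect_equal(gaf_dose(x, fit, depth_cm = 0), pairs$kerma_mGy,
               tolerance = max(abs(fit$residuals)) + 1e-9)

  expect_error(fit_gaf_calibration(data.frame(net_dR = c(0.5, 1.0, 0.2),
                                              kerma_mGy = 1:3)),
               class = "mammodose_gaf_domain")
  expect_warning(
    fit_gaf_calibration(data.frame(net_dR = c(0.05, 0.05, 0.1),
                                   kerma_mGy = c(1, 2, 3))),
    "degenerate")
})

test_that("film dose and uncertainty evaluate the published-style model", {
  cal <- gaf_calib_at_depth(0)
  # hand evaluation: 0.5676 + (-440.787) * 0.05/ln(0.05)
  expect_equal(gaf_dose(0.05, cal, depth_cm = 0), 7.9249, tolerance = 1e-4)
  # uncertainty at 10 mGy: 4.1906 + 19.0195 exp(-10/2.1823)
  expect_equal(gaf_uncertainty(10, cal, depth_cm = 0), 4.3852,
               tolerance = 1e-4)
  # asymptote equals the additive coefficient
  expect_equal(gaf_uncertainty(1e6, cal, depth_cm = 0), 4.1906,
               tolerance = 1e-6)
  # monotone decreasing toward the asymptote
  u <- gaf_uncertainty(seq(1, 10, by = 0.5), cal, depth_cm = 0)
  expect_true(all(diff(u) < 0))
  expect_true(all(u > 4.1906))

  expect_error(gaf_dose(-0.1, cal), class = "mammodose_gaf_domain")
})

test_that("depth-specific calibrations refuse cross-depth use", {
  cal <- gaf_calib_at_depth(2)
  expect_error(gaf_dose(0.05, cal, depth_cm = 0),
               class = "mammodose_depth_mismatch")
  expect_no_error(gaf_dose(0.05, cal, depth_cm = 0, override = TRUE))
  expect_no_error(gaf_dose(0.05, cal))  # unspecified depth is allowed

  tc <- tld_calib(0.0103, depth_cm = 2)
  expect_error(tld_dose(100, tc, depth_cm = 4),
               class = "mammodose_depth_mismatch")
})

test_that("TLD and MOSFET dose equations", {
  tc <- tld_calib(1.11e-2, S = 1)
  expect_equal(tld_dose(100, tc), 1.11)
  tc2 <- tld_calib(1.11e-2, S = 2)
  expect_equal(tld_dose(100, tc2), tld_dose(100, tc) / 2)
  expect_equal(mean(c(1.0, 1.1, 1.2)), 1.1)
  expect_error(tld_calib(1.11e-2, S = 0), class = "mammodose_calib_domain")

  mc <- mosfet_calib(2.07)
  expect_equal(mosfet_dose(c(2.07, 2.07, 2.07), mc), 1.0)
  mc2 <- mosfet_calib(2 * 2.07)
  expect_equal(mosfet_dose(c(2.07, 2.07, 2.07), mc2), 0.5)
  expect_equal(mosfet_dose(c(2, 4, 6), mosfet_calib(2)), 2.0)
  expect_warning(mosfet_dose(c(-1, 2, 3), mosfet_calib(2)), "inversion")
})

test_that("quadrature combination matches a brute-force oracle", {
  expect_equal(combine_uncertainty(c(3, 4)), 5)
  expect_equal(combine_uncertainty(7.3), 7.3)
  expect_equal(
    combine_uncertainty(data.frame(value = sqrt(3), type = "B")), 1,
    tolerance = 1e-12)

  set.seed(5)
  for (i in 1:20) {
    vals <- runif(sample(1:6, 1), 0, 8)
    types <- sample(c("A", "B"), length(vals), replace = TRUE)
    comp <- data.frame(value = vals, type = types)
    std <- ifelse(types == "B", vals / sqrt(3), vals)
    oracle <- sqrt(sum(std^2))  # direct quadrature, computed independently
    expect_equal(combine_uncertainty(comp), oracle, tolerance = 1e-12)
    # permutation invariance and >= max component
    perm <- sample(nrow(comp))
    expect_equal(combine_uncertainty(comp[perm, ]), oracle,
                 tolerance = 1e-12)
    expect_gte(oracle, max(std) - 1e-12)
  }
  expect_error(combine_uncertainty(numeric(0)), class = "mammodose_unc")
})

test_that("synthetic readings round-trip through each calibration", {
  gaf <- gaf_calib_at_depth(1)
  doses <- c(1.5, 3, 5, 8)
  clean <- synth_readings(doses, gaf, noise_pct = 0, seed = 4)
  expect_equal(gaf_dose(clean$net_dR, gaf, depth_cm = 1), doses,
               tolerance = 1e-8)
  again <- synth_readings(doses, gaf, noise_pct = 3, seed = 4)
  expect_identical(again,
                   synth_readings(doses, gaf, noise_pct = 3, seed = 4))
  expect_warning(
    expect_warning(synth_readings(0.2, gaf, seed = 1), "calibration range"),
    "zero-signal")

  tc <- tld_calib(1.04e-2, S = c(0.98, 1.02, 1.0))
  rt <- synth_readings(c(2, 4, 6), tc, noise_pct = 0, seed = 9)
  expect_equal(tld_dose(rt$Q_nC, tc), c(2, 4, 6), tolerance = 1e-12)

  mcal <- mosfet_calib(2.16)
  rm <- synth_readings(3, mcal, noise_pct = 0, seed = 2)
  expect_equal(rm$delta_V_mV / mcal$CF, 3, tolerance = 1e-12)
})

test_that("reconstruction error matches the injected noise level", {
  gaf <- gaf_calib_at_depth(0)
  doses <- rep(5, 1000)
  rd <- synth_readings(doses, gaf, noise_pct = 5, seed = 77)
  rec <- gaf_dose(rd$net_dR, gaf, depth_cm = 0)
  rmse <- sqrt(mean((rec / doses - 1)^2)) * 100
  expect_equal(rmse, 5, tolerance = 0.15)
  expect_lt(abs(mean(rec / doses - 1)), 0.006)  # unbiased
})

test_that("calibration recovery degrades smoothly with noise", {
  a <- 0.4796; b <- -382.102
  truth <- gaf_calib(a, b, depth_cm = 2)
  x <- c(0.012, 0.025, 0.04, 0.06, 0.085, 0.115, 0.15)
  doses <- gaf_dose(x, truth, depth_cm = 2)
  # zero noise: exact recovery
  rd0 <- suppressWarnings(synth_readings(doses, truth, noise_pct = 0, seed = 3))
  fit0 <- fit_gaf_calibration(
    data.frame(net_dR = rd0$net_dR, kerma_mGy = doses))
  expect_equal(fit0$a, a, tolerance = 1e-6)
  expect_equal(fit0$b, b, tolerance = 1e-6)
  # 1% noise: slope recovered within 2%
  set.seed(31)
  fitn <- fit_gaf_calibration(
    data.frame(net_dR = x, kerma_mGy = doses * (1 + rnorm(7, 0, 0.01))))
  expect_equal(fitn$b, b, tolerance = 0.02)
})
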