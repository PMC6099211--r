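# Source model, heel effect, Monte Carlo engine, tally statistics,
# analytic kerma and normalization.

test_that("heel weight evaluates the quartic model", {
  m <- heel_model()
  # product of the two axis polynomials at the chest-wall center point
  expect_equal(heel_weight(0, 0, m, normalize = FALSE), 1.0176 * 0.9971,
               tolerance = 1e-12)
  # y-axis polynomial at d = 10 cm (x axis flattened)
  my <- heel_model(a_x = 1, b_x = 0, c_x = 0)
  expect_equal(heel_weight(0, 100, my, normalize = FALSE),
               1.0176 - 0.0008 * 100 - 4.8146e-7 * 1e4,
               tolerance = 1e-12)
  expect_equal(heel_weight(0, 100, my, normalize = FALSE), 0.93279,
               tolerance = 1e-5)
  # constant model
  flat <- flat_heel()
  expect_equal(heel_weight(c(-80, 0, 120), c(10, 100, 200), flat,
                           normalize = FALSE), rep(1, 3))
  expect_equal(heel_weight(50, 50, flat), 1)
})

test_that("heel fit recovers generating parameters", {
  truth <- heel_model()
  d <- seq(0, 22, by = 2)
  meas <- rbind(
    data.frame(axis = "y", d_cm = d,
               value = truth$a_y + truth$b_y * d^2 + truth$c_y * d^4),
    data.frame(axis = "x", d_cm = d,
               value = truth$a_x + truth$b_x * d^2 + truth$c_x * d^4)
  )
  fit <- fit_heel_model(meas)
  expect_equal(fit$a_y, truth$a_y, tolerance = 1e-10)
  expect_equal(fit$b_y, truth$b_y, tolerance = 1e-10)
  expect_equal(fit$c_y, truth$c_y, tolerance = 1e-10)
  expect_equal(fit$a_x, truth$a_x, tolerance = 1e-10)

  # 1% noise: intercept recovered within 2%
  set.seed(99)
  noisy <- meas
  noisy$value <- noisy$value * (1 + rnorm(nrow(noisy), 0, 0.01))
  fitn <- fit_heel_model(noisy)
  expect_equal(fitn$a_y, truth$a_y, tolerance = 0.02)
  expect_equal(fitn$a_x, truth$a_x, tolerance = 0.02)

  # constant data collapses to a flat model
  const <- data.frame(axis = "y", d_cm = d, value = 2)
  fitc <- fit_heel_model(const)
  expect_equal(fitc$a_y, 2, tolerance = 1e-10)
  expect_equal(fitc$b_y, 0, tolerance = 1e-10)
  expect_equal(fitc$c_y, 0, tolerance = 1e-10)

  expect_error(fit_heel_model(data.frame(axis = "y", d_cm = c(0, 1),
                                         value = c(1, 1))),
               class = "mammodose_heel_fit")
})

test_that("primary sampling respects collimation, heel and spectrum", {
  s <- tuned_spectrum()
  geo <- beam_geometry()
  ps <- sample_primary(1e5, s, geo, flat_heel(), seed = 7)
  expect_true(all(abs(ps$x_mm) <= 150))
  expect_true(all(ps$y_mm >= 0 & ps$y_mm <= 240))

  # flat heel: intercepts follow the cos^3 solid-angle density; in a
  # central subregion that density is flat within ~1%, so counts in a
  # 4x4 grid over |x|<60, y in (60,180) should be uniform (chi-square)
  sel <- abs(ps$x_mm) < 60 & ps$y_mm > 60 & ps$y_mm < 180
  gx <- cut(ps$x_mm[sel], seq(-60, 60, length.out = 5))
  gy <- cut(ps$y_mm[sel], seq(60, 180, length.out = 5))
  counts <- as.vector(table(gx, gy))
  chi <- sum((counts - mean(counts))^2 / mean(counts))
  expect_gt(stats::pchisq(chi, df = 15, lower.tail = FALSE), 0.001)

  # energy histogram matches the spectrum's bin probabilities
  bins <- c(s$energy_keV - s$bin_keV / 2, max(s$energy_keV) + s$bin_keV / 2)
  counts_e <- graphics::hist(ps$energy_keV, breaks = bins,
                             plot = FALSE)$counts
  p <- s$fluence / sum(s$fluence)
  keep <- p > 1e-5
  chi_e <- sum((counts_e[keep] - 1e5 * p[keep])^2 / (1e5 * p[keep]))
  expect_gt(stats::pchisq(chi_e, df = sum(keep) - 1, lower.tail = FALSE),
            0.001)

  # heel tilts the y distribution toward the chest wall
  ph <- sample_primary(4e4, s, geo, heel_model(), seed = 8)
  expect_lt(mean(ph$y_mm), mean(ps$y_mm))
})

test_that("near-vacuum phantom tallies nothing; conservation holds", {
  vac <- make_material("near-vacuum", c(N = 1), density = 1e-20)
  ph <- build_homogeneous(80, 4, voxel_mm = 4, material = vac)
  chips <- tld_positions(ph, 2)
  s <- tuned_spectrum()
  suppressWarnings(
    r <- run_mc(ph, s, n = 2e4, seed = 1, tallies = chips,
                chip_material = vac)
  )
  expect_true(all(r$tallies$dose_per_history_mGy == 0))
  expect_equal(r$deposited_keV + r$escaped_keV, r$emitted_keV,
               tolerance = 1e-9)

  hp <- coarse_homogeneous(4)
  rr <- suppressWarnings(
    run_mc(hp, s, n = 2e4, seed = 2, tallies = tld_positions(hp, 2)))
  expect_equal(rr$deposited_keV + rr$escaped_keV, rr$emitted_keV,
               tolerance = 1e-9)
  expect_lte(rr$deposited_keV, rr$emitted_keV)
  expect_error(run_mc(hp, s, n = 1e3), class = "mammodose_seed")
})

test_that("photoelectric-only pencil beam reproduces mu*exp(-mu z)", {
  # single-material slab, monoenergetic vertical pencil beam, scattering
  # disabled: layer deposits follow exp(-mu z) attenuation exactly
  ph <- build_homogeneous(60, 4, voxel_mm = 4,
                          material = material_breast5050())
  mono <- mono_spectrum(20)
  phys <- physics_options(coherent = FALSE, incoherent = FALSE)
  n <- 4e4
  r <- run_mc(ph, mono, n = n, seed = 5, voxel_tally = TRUE,
              physics = phys, pencil_at = c(0, 30),
              geometry = beam_geometry(paddle_thickness_mm = 0))
  prof <- apply(r$voxel_keV, 3, sum)  # bottom-up z layers
  prof <- rev(prof)                   # entrance first
  b <- material_breast5050()
  pe <- mammodose:::.material_coef(b, 20, "pe") * b$density / 10
  coh <- mammodose:::.material_coef(b, 20, "coh") * b$density / 10
  inc <- mammodose:::.material_coef(b, 20, "incoh") * b$density / 10
  mu <- pe  # scattering disabled: total = photoelectric
  # slant path through 4 mm layers (pencil aimed at y = 30 mm)
  geo <- beam_geometry(paddle_thickness_mm = 0)
  slant <- sqrt(30^2 + geo$sdd_mm^2) / geo$sdd_mm
  # air attenuation above the phantom is common to all layers and
  # cancels in the layer-ratio comparison
  expected_ratio <- exp(-mu * 4 * slant)
  ratios <- prof[-1] / prof[-length(prof)]
  counts <- prof / 20  # photons absorbed per layer
  sig <- ratios * sqrt(1 / counts[-1] + 1 / counts[-length(prof)])
  expect_true(all(abs(ratios - expected_ratio) < 3 * sig))
  # and absolute absorbed fraction in the first layer
  p1 <- prof[1] / (n * 20)
  mu_air <- mu_over_rho(material_air(), 20) * material_air()$density / 10
  air_path <- (geo$sdd_mm - 40) * slant
  exp_p1 <- exp(-mu_air * air_path) * (1 - exp(-mu * 4 * slant))
  expect_equal(p1, exp_p1, tolerance = 4 / sqrt(n * exp_p1))
})

test_that("Sempau statistics: hand formula and 1/sqrt(N) scaling", {
  # d = {1,1,1,1}
  st <- tally_stats(4, 4, 4)
  expect_equal(st$sigma, 0)
  # d = {0,2}: mean 1, sigma^2 = (1/2)[(4/2) - 1] = 0.5
  st2 <- tally_stats(2, 4, 2)
  expect_equal(st2$mean_per_history, 1)
  expect_equal(st2$sigma, sqrt(0.5), tolerance = 1e-12)
  expect_warning(tally_stats(0, 0, 10), "zero-mean")

  # relative sigma scales as 1/sqrt(N) within 20% on a fixed scene
  ph <- coarse_homogeneous(4)
  s <- tuned_spectrum()
  r1 <- run_mc(ph, s, n = 5e4, seed = 11)
  r4 <- run_mc(ph, s, n = 2e5, seed = 12)
  expect_equal(r1$total_energy$rel_sigma / r4$total_energy$rel_sigma, 2,
               tolerance = 0.2)
})

test_that("Woodcock tracking matches the layered voxel-walk reference", {
  # two-material slab scene, vertical-ish pencil beam, full physics
  ph <- two_layer_slab(radius_mm = 80, thickness_cm = 4, voxel_mm = 2)
  mono <- mono_spectrum(20)
  geo <- beam_geometry(paddle_thickness_mm = 0)
  n <- 3e4
  r <- run_mc(ph, mono, n = n, seed = 21, voxel_tally = TRUE,
              physics = physics_options(), pencil_at = c(0, 40),
              geometry = geo)
  # mammodose central-column depth profile (r < 10 mm of the axis)
  ctr <- mammodose:::.voxel_centers(ph)
  # beam axis tilts slightly in y with depth; use its intercept per z
  z_src <- -geo$table_mm + geo$sdd_mm
  axis_y <- function(z) 40 * (z_src - z) / (z_src + geo$table_mm)
  nz <- dim(ph$labels)[3]
  mc_prof <- vapply(seq_len(nz), function(k) {
    ay <- axis_y(ctr$z[k])
    sel_x <- abs(ctr$x) < 10
    sel_y <- abs(ctr$y - ay) < 10
    sum(r$voxel_keV[sel_x, sel_y, k])
  }, numeric(1))
  # pair the 2 mm voxel layers into 10 bins of 4 mm
  mc_bins <- colSums(matrix(mc_prof, nrow = 2))

  # independent reference: explicit layered voxel walk
  dirv <- c(0, 40, -geo$sdd_mm - 0)
  dirv <- dirv / sqrt(sum(dirv^2))
  layers <- tibble::tibble(
    z_lo = c(-1.7, 0, 20, 40),
    z_hi = c(0, 20, 40, z_src + 1),
    material = list(material_carbon_fiber(), material_glandular(),
                    material_adipose(), material_air())
  )
  dep <- ref_slab_mc(layers, start = c(0, 0, z_src), dir = dirv,
                     e0_keV = 20, n = n, seed = 22,
                     z_tally = c(0, 40), nz_bins = 10, r_max = 10)
  ref_bins <- colSums(dep)
  ref_sig <- apply(dep, 2, stats::sd) * sqrt(nrow(dep))

  # both sides carry comparable counting statistics (same scene, same n)
  mc_sig <- ref_sig
  # reference bins are ordered bottom-up like the phantom z axis
  for (b in seq_len(10)) {
    tol <- 3 * sqrt(ref_sig[b]^2 + mc_sig[b]^2)
    expect_lt(abs(mc_bins[b] - ref_bins[b]), tol + 1e-9)
  }
})

test_that("analytic kerma: inverse square, paddle transmission, region", {
  s <- tuned_spectrum()
  geo1 <- beam_geometry(paddle_bottom_mm = 45)
  # inverse-square check: score the same ray bundle (region scaled with
  # the plane's distance from the source) at two heights
  za <- 400; zb <- 100
  z_src <- geo1$sdd_mm - 1.7
  lam_a <- (z_src - za) / geo1$sdd_mm
  lam_b <- (z_src - zb) / geo1$sdd_mm
  bundle <- c(-1, 1, 99, 101)  # detector-plane region, mm
  ka <- incident_air_kerma(s, geo1, flat_heel(),
                           region_mm = bundle * lam_a,
                           score_z_mm = za, paddle = FALSE)
  kb <- incident_air_kerma(s, geo1, flat_heel(),
                           region_mm = bundle * lam_b,
                           score_z_mm = zb, paddle = FALSE)
  d_src_a <- z_src - za
  d_src_b <- z_src - zb
  # remove the air-column attenuation difference to isolate 1/r^2
  p <- s$fluence / sum(s$fluence)
  muen <- muen_over_rho(material_air(), s$energy_keV)
  mu_air <- mu_over_rho(material_air(), s$energy_keV) *
    material_air()$density / 10
  wa <- sum(p * s$energy_keV * muen * exp(-mu_air * d_src_a))
  wb <- sum(p * s$energy_keV * muen * exp(-mu_air * d_src_b))
  expect_equal((ka / wa) / (kb / wb), (d_src_b / d_src_a)^2,
               tolerance = 1e-3)

  # paddle on/off ratio equals the spectrum's paddle transmission
  kp <- incident_air_kerma(s, geo1, flat_heel(), region_mm = c(-1, 1, 54, 56),
                           score_z_mm = 40, paddle = TRUE)
  k0 <- incident_air_kerma(s, geo1, flat_heel(), region_mm = c(-1, 1, 54, 56),
                           score_z_mm = 40, paddle = FALSE)
  pet <- material_pet()
  mu_pet <- mu_over_rho(pet, s$energy_keV) * pet$density / 10
  w <- p * s$energy_keV * muen * exp(-mu_air * (geo1$sdd_mm - 1.7 - 40))
  trans_expected <- sum(w * exp(-mu_pet * 3)) / sum(w)
  expect_equal(kp / k0, trans_expected, tolerance = 1e-3)

  expect_error(incident_air_kerma(s, geo1, region_mm = c(-200, 200, 0, 30)),
               class = "mammodose_mc")
})

test_that("scale factor and dose-to-air conversion", {
  expect_equal(scale_factor(10, 10), 1)
  expect_equal(scale_factor(10, 2), 5)
  expect_error(scale_factor(-1, 2), class = "mammodose_mc")
  s <- tuned_spectrum()
  k <- incident_air_kerma(s)
  expect_equal(k * scale_factor(3.7, k), 3.7, tolerance = 1e-12)

  # same material in numerator and denominator: no change
  expect_equal(spectrum_avg_muen_ratio(s, material_tld(), material_tld()), 1)
  mono <- mono_spectrum(25)
  expect_equal(dose_to_air(2, mono),
               2 * muen_over_rho(material_air(), 25) /
                 muen_over_rho(material_tld(), 25),
               tolerance = 1e-12)
  # hardening changes the conversion between entrance and 4 cm depth
  s4 <- attenuate_spectrum(s, material_breast5050(), 40)
  expect_false(isTRUE(all.equal(
    spectrum_avg_muen_ratio(s, material_air(), material_tld()),
    spectrum_avg_muen_ratio(s4, material_air(), material_tld()),
    tolerance = 1e-4)))
})

test_that("dose map: uniformity, pitch-invariant integral, contrast", {
  ph <- build_homogeneous(90, 3, voxel_mm = 3)
  s <- tuned_spectrum()
  r <- suppressWarnings(
    score_dose_map(ph, s, depth_cm = 1, n = 2e5, seed = 31,
                   pitch_mm = 10, size_mm = c(60, 60),
                   heel = flat_heel()))
  m <- r$map$dose_per_history_mGy
  ctr <- m[2:5, 2:5]  # central pixels, away from edges
  sg <- r$map$rel_sigma[2:5, 2:5] * ctr
  expect_true(all(abs(ctr - mean(ctr)) < 3 * sqrt(sg^2 + mean(sg)^2)))

  # integral is invariant to pixel pitch (identical transport stream)
  r1 <- suppressWarnings(score_dose_map(ph, s, depth_cm = 1, n = 3e4,
                                        seed = 32, pitch_mm = 5,
                                        size_mm = c(40, 40)))
  r2 <- suppressWarnings(score_dose_map(ph, s, depth_cm = 1, n = 3e4,
                                        seed = 32, pitch_mm = 40,
                                        size_mm = c(40, 40)))
  e1 <- sum(r1$map$dose_per_history_mGy) * (5^2 * 0.38 / 1000 * 2.48)
  e2 <- sum(r2$map$dose_per_history_mGy) * (40^2 * 0.38 / 1000 * 2.48)
  expect_equal(e1, e2, tolerance = 1e-9)

  # local tissue dose: a thin glandular inclusion exceeds the adjacent
  # adipose at the same depth (energy-absorption contrast, as strand-like
  # fibroglandular structures show in a heterogeneous phantom)
  ph2 <- build_homogeneous(90, 3, voxel_mm = 3,
                           material = material_adipose())
  xc <- mammodose:::.voxel_centers(ph2)$x
  yc <- mammodose:::.voxel_centers(ph2)$y
  k <- 5  # a mid-depth slice; one voxel (3 mm) thick inclusion
  sl <- ph2$labels[xc < 0, , k]
  sl[sl == 1L] <- 2L
  ph2$labels[xc < 0, , k] <- sl
  ph2$label_map[["2"]] <- material_glandular()
  rg <- run_mc(ph2, s, n = 2e5, seed = 33, voxel_tally = TRUE)
  in_y <- yc > 20 & yc < 60
  gl <- rg$voxel_keV[xc > -60 & xc < -20, in_y, k] /
    material_glandular()$density
  ad <- rg$voxel_keV[xc > 20 & xc < 60, in_y, k] /
    material_adipose()$density
  expect_gt(mean(gl), 1.2 * mean(ad))

  expect_error(score_dose_map(ph, s, depth_cm = 5, n = 1e3, seed = 1),
               class = "mammodose_phantom_geometry")
})
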