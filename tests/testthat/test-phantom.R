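# Phantom construction, glandularity accounting, serialization.

test_that("homogeneous semicylinder voxelizes to the analytic volume", {
  ph <- coarse_homogeneous(voxel_mm = 2)
  v_analytic <- pi / 2 * 10^2 * 5  # cm^3
  v_voxel <- sum(ph$labels == 1L) * 0.2^3
  expect_equal(v_voxel, v_analytic, tolerance = 0.01)
  expect_equal(sort(unique(as.integer(ph$labels))), c(0L, 1L))
  expect_error(build_homogeneous(100, 0), class = "mammodose_phantom_geometry")
  expect_error(build_homogeneous(100, 5, voxel_mm = 300),
               class = "mammodose_phantom_geometry")
})

test_that("voxelization error shrinks with voxel size", {
  v_analytic <- pi / 2 * 10^2 * 5
  err <- vapply(c(4, 2, 1), function(v) {
    ph <- build_homogeneous(100, 5, voxel_mm = v)
    abs(sum(ph$labels == 1L) * (v / 10)^3 - v_analytic) / v_analytic
  }, numeric(1))
  expect_lt(err[2], err[1])
  expect_lt(err[3], err[2] * 1.05)
})

test_that("synthetic breast hits the target glandularity across seeds", {
  for (seed in 1:10) {
    sb <- build_synthetic_breast(seed = seed, voxel_mm = 2.5)
    expect_gt(glandular_mass_fraction(sb), 0.104)
    expect_lt(glandular_mass_fraction(sb), 0.114)
  }
})

test_that("synthetic breast is reproducible and handles edge targets", {
  a <- build_synthetic_breast(seed = 42, voxel_mm = 3)
  b <- build_synthetic_breast(seed = 42, voxel_mm = 3)
  expect_identical(a$labels, b$labels)
  c <- build_synthetic_breast(seed = 43, voxel_mm = 3)
  expect_false(identical(a$labels, c$labels))

  pure <- build_synthetic_breast(seed = 1, voxel_mm = 3,
                                 target_glandularity = 0)
  expect_equal(sum(pure$labels == 2L), 0)
  expect_equal(glandular_mass_fraction(pure), 0)
  expect_error(build_synthetic_breast(seed = 1, target_glandularity = 1.2),
               class = "mammodose_phantom_geometry")
})

test_that("glandular mass fraction handles trivial phantoms", {
  ph <- build_homogeneous(50, 2, voxel_mm = 2,
                          material = material_glandular())
  expect_equal(glandular_mass_fraction(ph), 1)

  # 50/50-by-volume equal-density two-tissue phantom
  eq_g <- make_material("g", c(O = 1), 1.0, glandular_fraction = 1)
  eq_a <- make_material("a", c(C = 1), 1.0)
  ph2 <- build_homogeneous(50, 2, voxel_mm = 2, material = eq_g)
  nz <- dim(ph2$labels)[3]
  sl <- ph2$labels[, , seq_len(nz / 2)]
  sl[sl == 1L] <- 2L
  ph2$labels[, , seq_len(nz / 2)] <- sl
  ph2$label_map[["2"]] <- eq_a
  expect_equal(glandular_mass_fraction(ph2), 0.5, tolerance = 1e-9)
})

test_that("homogenize conserves glandular mass and is a fixed point", {
  sb <- build_synthetic_breast(seed = 5, voxel_mm = 2.5)
  hb <- homogenize(sb)
  expect_equal(glandular_mass_fraction(hb), glandular_mass_fraction(sb),
               tolerance = 1e-3)
  # interior is one uniform mixture label
  interior_labels <- unique(as.integer(hb$labels))
  expect_lte(length(interior_labels), 3)  # air, mixture, skin
  # tissue mass conserved within 0.5%
  mass <- function(p) {
    st <- mammodose:::.tissue_label_stats(p)
    sum(st$n * st$rho)
  }
  expect_equal(mass(hb), mass(sb), tolerance = 5e-3)

  h2 <- homogenize(hb)
  m1 <- hb$label_map[[as.character(setdiff(interior_labels, c(0L, 3L)))]]
  m2 <- h2$label_map[["1"]]
  expect_equal(m2$mass_fractions[sort(names(m2$mass_fractions))],
               m1$mass_fractions[sort(names(m1$mass_fractions))],
               tolerance = 1e-9)
  expect_equal(glandular_mass_fraction(h2), glandular_mass_fraction(hb),
               tolerance = 1e-9)
})

test_that("TLD placement: 30 chips, inside footprint, errors named", {
  ph <- coarse_homogeneous(2)
  chips <- tld_positions(ph, depth_cm = 2)
  expect_equal(nrow(chips), 30)
  # every chip corner stays inside the semicircle and the slab
  for (i in seq_len(nrow(chips))) {
    cx <- abs(chips$x_mm[i]) + chips$dx_mm[i] / 2
    cy <- chips$y_mm[i] + chips$dy_mm[i] / 2
    expect_lte(cx^2 + cy^2, 100^2)
    expect_gte(chips$y_mm[i] - chips$dy_mm[i] / 2, 0)
    expect_gte(chips$z_mm[i] - chips$dz_mm[i] / 2, 0)
    expect_lte(chips$z_mm[i] + chips$dz_mm[i] / 2, 50)
  }
  empty <- tld_positions(ph, 2, layout = tibble::tibble(x_mm = numeric(),
                                                        y_mm = numeric()))
  expect_equal(nrow(empty), 0)

  bad <- tibble::tibble(x_mm = c(0, 0), y_mm = c(20, 150))
  err <- tryCatch(tld_positions(ph, 2, layout = bad),
                  error = function(e) conditionMessage(e))
  expect_match(err, "position 2")
})

test_that("phantom files round trip losslessly and reject corruption", {
  sb <- build_synthetic_breast(seed = 3, voxel_mm = 3)
  path <- withr::local_tempfile(fileext = ".raw")
  write_phantom(sb, path)
  back <- read_phantom(path)
  expect_identical(back$labels, sb$labels)
  expect_equal(back$voxel_mm, sb$voxel_mm)
  expect_equal(back$origin_mm, sb$origin_mm)
  expect_equal(back$label_map[["2"]]$mass_fractions,
               sb$label_map[["2"]]$mass_fractions)

  # truncated raw file
  raw <- readBin(path, "raw", n = 1e9)
  writeBin(raw[seq_len(length(raw) - 10)], path)
  expect_error(read_phantom(path), class = "mammodose_format")

  # sidecar missing a label
  write_phantom(sb, path)
  sc <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  sc$label_map[["2"]] <- NULL
  jsonlite::write_json(sc, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  expect_error(read_phantom(path), class = "mammodose_format")
})
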