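## R interface to the Monte Carlo photon transport engine.
##
## The engine (src/transport.cpp) tracks photons from a heel-weighted
## collimated point source through the compression paddle, the voxelized
## phantom (with TLD-chip and dose-map-layer material overrides) and the
## carbon-fiber support table, using Woodcock (delta) tracking with
## z-zoned majorant cross sections. Energy transferred to electrons is
## deposited locally (kerma approximation), photons below 1 keV are
## absorbed on the spot, and tallies are accumulated history by history
## so the statistical uncertainty follows the history-scores method.

#' Beam geometry of the simulated mammography unit
#'
#' Defaults reproduce a clinical mammography geometry: isotropic point
#' source 655.5 mm above the detector, collimated to a 300 x 240 mm field
#' at the detector plane (x lateral and centered, y from the chest-wall
#' edge), a 3 mm polyethylene-terephthalate compression paddle and a
#' 1.7 mm carbon-fiber breast-support table.
#'
#' @param source_to_detector_mm source-detector distance (mm).
#' @param field_mm field width (x) and length (y) at the detector plane.
#' @param paddle_thickness_mm compression paddle thickness (mm).
#' @param table_thickness_mm support table thickness (mm).
#' @param paddle_gap_mm air gap between phantom top and paddle bottom.
#' @param paddle_bottom_mm paddle-bottom height above the table top, used
#'   when no phantom fixes it (free-in-air kerma geometry).
#' @return A `beam_geometry` object.
#' @export
beam_geometry <- function(source_to_detector_mm = 655.5,
                          field_mm = c(300, 240),
                          paddle_thickness_mm = 3,
                          table_thickness_mm = 1.7,
                          paddle_gap_mm = 0,
                          paddle_bottom_mm = 45) {
  structure(
    list(sdd_mm = source_to_detector_mm, field_mm = field_mm,
         paddle_mm = paddle_thickness_mm, table_mm = table_thickness_mm,
         paddle_gap_mm = paddle_gap_mm,
         paddle_bottom_mm = paddle_bottom_mm),
    class = "beam_geometry"
  )
}

#' Anode heel-effect model
#'
#' Separable quartic model of the field-intensity modulation,
#' `HE(d) = a + b d^2 + c d^4` with `d` in cm, applied along y (distance
#' from the chest-wall edge) and along x (distance from the lateral
#' centerline) and combined multiplicatively. Defaults are the fitted
#' values for the modelled clinical unit (y axis r^2 = 0.99, x axis
#' r^2 = 0.81).
#'
#' @param a_y,b_y,c_y y-axis (chest wall to nipple) coefficients.
#' @param a_x,b_x,c_x x-axis (lateral) coefficients.
#' @return A `heel_model` object.
#' @export
heel_model <- function(a_y = 1.0176, b_y = -0.0008, c_y = -4.8146e-7,
                       a_x = 0.9971, b_x = -0.0002, c_x = -3.9390e-7) {
  structure(
    list(a_y = a_y, b_y = b_y, c_y = c_y, a_x = a_x, b_x = b_x, c_x = c_x),
    class = "heel_model"
  )
}

#' Flat (no heel) model
#' @export
flat_heel <- function() heel_model(1, 0, 0, 1, 0, 0)

.heel_raw <- function(x_mm, y_mm, model) {
  dy <- y_mm / 10
  dx <- abs(x_mm) / 10
  he_y <- model$a_y + model$b_y * dy^2 + model$c_y * dy^4
  he_x <- model$a_x + model$b_x * dx^2 + model$c_x * dx^4
  he_y * he_x
}

#' Heel-effect weight at a field point
#'
#' The product of the two 1D heel polynomials evaluated at the point's
#' distances (`d_y` from the chest-wall edge, `d_x` from the lateral
#' centerline, both converted to cm). With `normalize = TRUE` the weight
#' is divided by its mean over the field so it integrates to unity.
#'
#' @param x_mm,y_mm point coordinates at the detector plane (mm).
#' @param model a `heel_model`.
#' @param field_mm field size used for normalization.
#' @param normalize divide by the field-mean weight?
#' @export
heel_weight <- function(x_mm, y_mm, model = heel_model(),
                        field_mm = c(300, 240), normalize = TRUE) {
  w <- .heel_raw(x_mm, y_mm, model)
  if (any(w <= 0 & abs(x_mm) <= field_mm[1] / 2 & y_mm <= field_mm[2])) {
    abort("heel weight nonpositive inside the field",
          class = "mammodose_heel_domain")
  }
  if (!normalize) {
    return(w)
  }
  gx <- seq(-field_mm[1] / 2, field_mm[1] / 2, length.out = 101)
  gy <- seq(0, field_mm[2], length.out = 101)
  norm <- mean(outer(gx, gy, function(x, y) .heel_raw(x, y, model)))
  w / norm
}

#' Fit the heel model to measured profiles
#'
#' Per-axis linear least squares of `HE(d) = a + b d^2 + c d^4` on air
#' kerma (or relative intensity) profiles. The input holds one row per
#' measurement with the axis it belongs to.
#'
#' @param measurements data frame with columns `axis` (`"x"` or `"y"`),
#'   `d_cm` (distance, cm) and `value`.
#' @return A `heel_model`; per-axis `r.squared` is attached as the
#'   `"r2"` attribute.
#' @export
fit_heel_model <- function(measurements) {
  stopifnot(all(c("axis", "d_cm", "value") %in% names(measurements)))
  fits <- list()
  r2 <- c()
  for (ax in c("y", "x")) {
    d <- measurements[measurements$axis == ax, ]
    if (nrow(d) == 0L) {
      fits[[ax]] <- c(1, 0, 0)
      next
    }
    if (length(unique(d$d_cm)) < 3) {
      abort(sprintf("axis '%s' needs >= 3 distinct distances", ax),
            class = "mammodose_heel_fit")
    }
    f <- lm(value ~ I(d_cm^2) + I(d_cm^4), data = d)
    fits[[ax]] <- unname(coef(f))
    ss_tot <- sum((d$value - mean(d$value))^2)
    r2[ax] <- if (ss_tot > 0) 1 - sum(stats::residuals(f)^2) / ss_tot else 1
  }
  out <- heel_model(a_y = fits$y[1], b_y = fits$y[2], c_y = fits$y[3],
                    a_x = fits$x[1], b_x = fits$x[2], c_x = fits$x[3])
  attr(out, "r2") <- r2
  out
}

#' @method tidy heel_model
#' @export
tidy.heel_model <- function(x, ...) {
  tibble(axis = rep(c("y", "x"), each = 3),
         term = rep(c("a", "b", "c"), 2),
         estimate = c(x$a_y, x$b_y, x$c_y, x$a_x, x$b_x, x$c_x))
}

#' Physics options for the transport engine
#'
#' @param cutoff_keV photon energy cutoff; photons below it are absorbed
#'   locally.
#' @param coherent,incoherent enable the scattering channels (disabling
#'   one removes its cross section entirely, for validation scenarios).
#' @export
physics_options <- function(cutoff_keV = 1, coherent = TRUE,
                            incoherent = TRUE) {
  list(cutoff_keV = cutoff_keV, coherent = coherent, incoherent = incoherent)
}

## ---- cross-section preparation -------------------------------------------

.EGRID <- list(e0 = 1, de = 0.05, n = 781)  # 1 to 40 keV

# per-material linear coefficients (1/mm) on the uniform grid, honoring
# disabled channels; returns list(mu, p_pe, p_pecoh) matrices
.prepare_xsec <- function(materials, physics) {
  eg <- .EGRID
  energies <- eg$e0 + eg$de * (seq_len(eg$n) - 1)
  nm <- length(materials)
  mu <- matrix(0, nm, eg$n)
  p_pe <- matrix(1, nm, eg$n)
  p_pecoh <- matrix(1, nm, eg$n)
  for (i in seq_len(nm)) {
    m <- materials[[i]]
    pe <- .material_coef(m, energies, "pe")
    coh <- if (physics$coherent) .material_coef(m, energies, "coh") else 0
    incoh <- if (physics$incoherent) .material_coef(m, energies, "incoh") else 0
    tot <- pe + coh + incoh
    mu[i, ] <- tot * m$density / 10
    p_pe[i, ] <- pe / tot
    p_pecoh[i, ] <- (pe + coh) / tot
  }
  list(e0 = eg$e0, de = eg$de, n = eg$n, energies = energies,
       mu = mu, p_pe = p_pe, p_pecoh = p_pecoh)
}

## ---- world / source assembly ----------------------------------------------

.build_run_spec <- function(phantom, spectrum, tallies, geometry, heel,
                            physics, map, chip_material = material_tld()) {
  # material table: 1 air, 2 paddle, 3 table, then phantom labels, chips/map
  mats <- list(material_air(), material_pet(), material_carbon_fiber())
  air_i <- 0L
  paddle_i <- 1L
  table_i <- 2L

  phantom_spec <- NULL
  ph_top <- 0
  if (!is.null(phantom)) {
    lbls <- sort(unique(as.integer(phantom$labels)))
    label2mat <- integer(max(lbls) + 1L)
    for (l in lbls) {
      m <- phantom$label_map[[as.character(l)]]
      mats[[length(mats) + 1L]] <- m
      label2mat[l + 1L] <- length(mats) - 1L
    }
    ph_top <- dim(phantom$labels)[3] * phantom$voxel_mm +
      phantom$origin_mm[3]
    phantom_spec <- list(
      labels = as.integer(phantom$labels),
      dims = dim(phantom$labels),
      origin = phantom$origin_mm,
      voxel_mm = phantom$voxel_mm,
      label2mat = label2mat
    )
  }

  chip_spec <- NULL
  chip_band <- NULL
  chip_mass_g <- NULL
  if (!is.null(tallies) && nrow(tallies) > 0) {
    tld <- chip_material
    mats[[length(mats) + 1L]] <- tld
    chip_i <- length(mats) - 1L
    centers <- cbind(tallies$x_mm, tallies$y_mm, tallies$z_mm)
    half <- cbind(tallies$dx_mm, tallies$dy_mm, tallies$dz_mm) / 2
    chip_spec <- list(centers = centers, half_dims = half, mat = chip_i)
    chip_band <- c(min(centers[, 3] - half[, 3]),
                   max(centers[, 3] + half[, 3]))
    chip_mass_g <- tallies$dx_mm * tallies$dy_mm * tallies$dz_mm / 1000 *
      tld$density
  }

  map_spec <- NULL
  map_band <- NULL
  if (!is.null(map)) {
    tld <- material_tld()
    mats[[length(mats) + 1L]] <- tld
    map_i <- length(mats) - 1L
    map_spec <- list(
      z_lo = map$z_lo, z_hi = map$z_hi, x_lo = map$x_lo, y_lo = map$y_lo,
      pitch_mm = map$pitch_mm, nx = map$nx, ny = map$ny, mat = map_i)
    map_band <- c(map$z_lo, map$z_hi)
  }

  # paddle position
  paddle_lo <- if (!is.null(phantom)) {
    ph_top + geometry$paddle_gap_mm
  } else {
    geometry$paddle_bottom_mm
  }
  paddle_hi <- paddle_lo + geometry$paddle_mm
  z_det <- -geometry$table_mm
  z_src <- z_det + geometry$sdd_mm

  slabs <- rbind(
    c(paddle_lo, paddle_hi, paddle_i),
    c(z_det, 0, table_i)
  )

  xw <- geometry$field_mm[1] / 2 + 60
  bounds <- c(xw, -30, geometry$field_mm[2] + 60, z_det, z_src + 1)

  world <- list(air_mat = air_i, phantom = phantom_spec, slabs = slabs,
                chips = chip_spec, map = map_spec, bounds = bounds)

  # z zones with per-zone majorant bands
  xs <- .prepare_xsec(mats, physics)
  breaks <- c(z_det, 0)
  if (!is.null(phantom)) breaks <- c(breaks, phantom$origin_mm[3], ph_top)
  if (!is.null(chip_band)) breaks <- c(breaks, chip_band)
  if (!is.null(map_band)) breaks <- c(breaks, map_band)
  breaks <- c(breaks, paddle_lo, paddle_hi, z_src + 1)
  breaks <- sort(unique(pmin(pmax(breaks, z_det), z_src + 1)))
  breaks <- breaks[c(TRUE, diff(breaks) > 1e-9)]
  n_zone <- length(breaks) - 1
  zone_maj <- matrix(0, n_zone, xs$n)
  overlaps <- function(lo, hi, band) {
    !is.null(band) && lo < band[2] - 1e-9 && hi > band[1] + 1e-9
  }
  for (zi in seq_len(n_zone)) {
    lo <- breaks[zi]; hi <- breaks[zi + 1]
    rows <- air_i + 1L
    if (overlaps(lo, hi, c(z_det, 0))) rows <- c(rows, table_i + 1L)
    if (overlaps(lo, hi, c(paddle_lo, paddle_hi))) {
      rows <- c(rows, paddle_i + 1L)
    }
    if (!is.null(phantom) &&
        overlaps(lo, hi, c(phantom$origin_mm[3], ph_top))) {
      rows <- c(rows, unique(phantom_spec$label2mat) + 1L)
    }
    if (overlaps(lo, hi, chip_band)) rows <- c(rows, chip_spec$mat + 1L)
    if (overlaps(lo, hi, map_band)) rows <- c(rows, map_spec$mat + 1L)
    zone_maj[zi, ] <- apply(xs$mu[rows, , drop = FALSE], 2, max)
  }
  xsec <- list(e0 = xs$e0, de = xs$de, n = xs$n, mu = xs$mu,
               p_pe = xs$p_pe, p_pecoh = xs$p_pecoh,
               zone_lo = breaks[-length(breaks)], zone_hi = breaks[-1],
               zone_maj = zone_maj)

  source_spec <- list(
    source_pos = c(0, 0, z_src), z_det = z_det,
    field = c(-geometry$field_mm[1] / 2, geometry$field_mm[1] / 2,
              0, geometry$field_mm[2]),
    heel = c(heel$a_y, heel$b_y, heel$c_y, heel$a_x, heel$b_x, heel$c_x),
    e_centers = spectrum$energy_keV,
    e_cdf = cumsum(spectrum$fluence) / sum(spectrum$fluence),
    bin_half = spectrum$bin_keV / 2
  )

  list(world = world, source = source_spec, xsec = xsec,
       chip_mass_g = chip_mass_g, z_src = z_src, z_det = z_det,
       paddle_lo = paddle_lo)
}

#' Sample primary photons
#'
#' Draws detector-plane intercepts and energies from the collimated,
#' heel-weighted source, for validating the source model.
#'
#' @param n number of photons.
#' @param spectrum an `xray_spectrum`.
#' @param geometry a `beam_geometry`.
#' @param heel a `heel_model`.
#' @param seed mandatory integer seed.
#' @return Tibble with `x_mm`, `y_mm` (detector-plane intercept) and
#'   `energy_keV`.
#' @export
sample_primary <- function(n, spectrum, geometry = beam_geometry(),
                           heel = heel_model(), seed) {
  if (missing(seed)) abort("seed is mandatory", class = "mammodose_seed")
  spec <- .build_run_spec(NULL, spectrum, NULL, geometry, heel,
                          physics_options(), NULL)
  out <- cpp_sample_primary(spec$source, as.integer(n), as.double(seed))
  as_tibble(out)
}

#' Run the Monte Carlo simulation
#'
#' Transports `n` photon histories through the beam geometry and phantom,
#' scoring dose (mGy per history) in the TLD-chip sensitive volumes, the
#' optional pixelized map layer, and optionally every phantom voxel.
#' Uncertainties are history-by-history standard deviations of the mean.
#'
#' @param phantom a `voxel_phantom`, or `NULL` for a free-in-air run.
#' @param spectrum an `xray_spectrum`.
#' @param n number of histories (>= 1).
#' @param seed mandatory integer seed.
#' @param tallies sensitive volumes from [tld_positions()], or `NULL`.
#' @param geometry a `beam_geometry`.
#' @param heel a `heel_model`.
#' @param physics a [physics_options()] list.
#' @param voxel_tally score energy deposition per phantom voxel (needed
#'   for glandular-dose evaluation)?
#' @param map a map-layer request from [score_dose_map()]'s internals, or
#'   `NULL`.
#' @param pencil_at optional `c(x_mm, y_mm)`: collapse the field to a
#'   vertical pencil beam aimed at this detector-plane point.
#' @param chip_material material filling the sensitive volumes
#'   (LiF:Mg,Cu,P by default, mirroring physical TLD chips).
#' @return An `mc_result`: tallies tibble, conservation totals (keV),
#'   optional voxel deposition array and map matrices, and run metadata.
#' @export
run_mc <- function(phantom, spectrum, n, seed, tallies = NULL,
                   geometry = beam_geometry(), heel = heel_model(),
                   physics = physics_options(), voxel_tally = FALSE,
                   map = NULL, pencil_at = NULL,
                   chip_material = material_tld()) {
  if (missing(seed)) {
    abort("seed is mandatory for reproducibility", class = "mammodose_seed")
  }
  if (n < 1) abort("n must be >= 1", class = "mammodose_mc")
  if (!is.null(tallies) && nrow(tallies) > 0) {
    mass <- tallies$dx_mm * tallies$dy_mm * tallies$dz_mm
    if (any(mass <= 0)) {
      abort("tally of zero mass", class = "mammodose_mc")
    }
  }
  spec <- .build_run_spec(phantom, spectrum, tallies, geometry, heel,
                          physics, map, chip_material)
  if (!is.null(pencil_at)) {
    spec$source$field <- c(pencil_at[1], pencil_at[1],
                           pencil_at[2], pencil_at[2])
  }
  raw <- cpp_run_mc(spec$world, spec$source, spec$xsec,
                    list(cutoff_keV = physics$cutoff_keV),
                    as.double(n), as.double(seed), isTRUE(voxel_tally))

  conv <- 1.602176634e-10  # keV/g -> mGy
  res <- list(
    n = n, seed = seed,
    emitted_keV = raw$emitted_keV,
    deposited_keV = raw$deposited_keV,
    escaped_keV = raw$escaped_keV,
    total_energy = tally_stats(raw$etot_sum, raw$etot_sum2, n)
  )
  if (!is.null(tallies) && nrow(tallies) > 0) {
    st <- tally_stats(raw$chip_sum_keV, raw$chip_sum2_keV2, n)
    res$tallies <- dplyr::bind_cols(
      tallies,
      tibble(
        dose_per_history_mGy = st$mean_per_history / spec$chip_mass_g * conv,
        rel_sigma = st$rel_sigma
      )
    )
  }
  if (!is.null(map)) {
    st <- tally_stats(raw$map_sum_keV, raw$map_sum2_keV2, n)
    pix_mass <- map$pitch_mm^2 * (map$z_hi - map$z_lo) / 1000 *
      material_tld()$density
    res$map <- list(
      dose_per_history_mGy = matrix(st$mean_per_history / pix_mass * conv,
                                    map$nx, map$ny),
      rel_sigma = matrix(st$rel_sigma, map$nx, map$ny),
      x_mm = map$x_lo + (seq_len(map$nx) - 0.5) * map$pitch_mm,
      y_mm = map$y_lo + (seq_len(map$ny) - 0.5) * map$pitch_mm
    )
  }
  if (isTRUE(voxel_tally) && !is.null(raw$voxel_keV)) {
    res$voxel_keV <- array(raw$voxel_keV, dim(phantom$labels))
  }
  structure(res, class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf(
    "<mc_result> %g histories (seed %g)\n  emitted %.4g keV, deposited %.4g keV, escaped %.4g keV\n",
    x$n, x$seed, x$emitted_keV, x$deposited_keV, x$escaped_keV))
  if (!is.null(x$tallies)) {
    cat(sprintf("  %d sensitive volumes, mean rel. sigma %.3g\n",
                nrow(x$tallies), mean(x$tallies$rel_sigma, na.rm = TRUE)))
  }
  invisible(x)
}

#' History-by-history tally statistics
#'
#' Mean score per history and its relative standard uncertainty from the
#' per-history sums `sum(d)` and `sum(d^2)`:
#' `sigma^2 = (1/N) (sum(d^2)/N - (sum(d)/N)^2)`.
#'
#' @param sum_d per-tally sum of per-history scores.
#' @param sum_d2 per-tally sum of squared per-history scores.
#' @param n number of histories (>= 2 for an uncertainty).
#' @return Tibble with `mean_per_history`, `sigma`, `rel_sigma`
#'   (`NA` with a warning where the mean is zero).
#' @export
tally_stats <- function(sum_d, sum_d2, n) {
  if (n < 2) abort("need at least 2 histories", class = "mammodose_mc")
  m <- sum_d / n
  var <- pmax(sum_d2 / n - m^2, 0) / n
  s <- sqrt(var)
  rel <- ifelse(m > 0, s / m, NA_real_)
  if (any(m == 0)) {
    warn("zero-mean tally: relative uncertainty undefined")
  }
  tibble(mean_per_history = m, sigma = s, rel_sigma = rel)
}

#' Analytic incident air kerma
#'
#' Free-in-air air kerma per history in a scoring region under the
#' compression paddle (default: 3 x 3 cm^2, laterally centered, starting
#' 4 cm from the chest-wall edge). Evaluated analytically: the
#' per-history primary fluence at the scoring plane (source collimation,
#' heel weighting and inverse square), attenuated by the paddle and the
#' air column, folded with `E (muen/rho)_air(E)`.
#'
#' @param spectrum an `xray_spectrum`.
#' @param geometry a `beam_geometry`.
#' @param heel a `heel_model`.
#' @param region_mm scoring region `c(x_lo, x_hi, y_lo, y_hi)` (mm).
#' @param score_z_mm scoring height above the table top; default just
#'   under the paddle bottom.
#' @param paddle include paddle attenuation?
#' @param n_quad quadrature points per region axis.
#' @return Air kerma in mGy per history.
#' @export
incident_air_kerma <- function(spectrum, geometry = beam_geometry(),
                               heel = heel_model(),
                               region_mm = c(-15, 15, 40, 70),
                               score_z_mm = NULL, paddle = TRUE,
                               n_quad = 15) {
  field <- geometry$field_mm
  if (region_mm[1] < -field[1] / 2 || region_mm[2] > field[1] / 2 ||
      region_mm[3] < 0 || region_mm[4] > field[2]) {
    abort("scoring region outside the field", class = "mammodose_mc")
  }
  z_det <- -geometry$table_mm
  z_src <- z_det + geometry$sdd_mm
  z_s <- score_z_mm %||% (geometry$paddle_bottom_mm - 0.1)

  # field-integrated source weight (normalizes the sampling density)
  gx <- seq(-field[1] / 2, field[1] / 2, length.out = 121)
  gy <- seq(0, field[2], length.out = 121)
  wfun <- function(x, y) {
    r2 <- x^2 + y^2 + (z_det - z_src)^2
    c3 <- (abs(z_det - z_src) / sqrt(r2))^3
    .heel_raw(x, y, heel) * c3
  }
  W <- mean(outer(gx, gy, wfun)) * field[1] * field[2]

  lam <- (z_s - z_src) / (z_det - z_src)  # scoring-plane scale factor
  air <- material_air()
  e <- spectrum$energy_keV
  p <- spectrum$fluence / sum(spectrum$fluence)
  muen <- muen_over_rho(air, e)
  mu_air <- mu_over_rho(air, e) * air$density / 10   # 1/mm
  pet <- material_pet()
  mu_pet <- mu_over_rho(pet, e) * pet$density / 10

  qx <- seq(region_mm[1], region_mm[2], length.out = n_quad)
  qy <- seq(region_mm[3], region_mm[4], length.out = n_quad)
  k_acc <- 0
  for (xs in qx) {
    for (ys in qy) {
      xd <- xs / lam
      yd <- ys / lam
      r2 <- xd^2 + yd^2 + (z_det - z_src)^2
      cth <- abs(z_det - z_src) / sqrt(r2)
      f <- wfun(xd, yd) / W             # per detector mm^2 per history
      phi <- f / (lam^2 * cth) * 100    # fluence at the plane, 1/cm^2
      slant_air <- (z_src - z_s - if (paddle) geometry$paddle_mm else 0) / cth
      slant_pet <- if (paddle) geometry$paddle_mm / cth else 0
      trans <- exp(-mu_air * slant_air - mu_pet * slant_pet)
      k_acc <- k_acc + phi * sum(p * e * muen * trans)
    }
  }
  k_acc / (n_quad^2) * 1.602176634e-10
}

#' Normalization scale factor
#'
#' Ratio of the measured incident air kerma to the simulated per-history
#' incident air kerma; multiplying per-history Monte Carlo doses by this
#' factor yields absolute doses in mGy.
#'
#' @param measured_kerma_mGy ionization-chamber air kerma (mGy).
#' @param simulated_kerma_per_history per-history analytic kerma (mGy).
#' @export
scale_factor <- function(measured_kerma_mGy, simulated_kerma_per_history) {
  if (measured_kerma_mGy <= 0 || simulated_kerma_per_history <= 0) {
    abort("kerma values must be > 0", class = "mammodose_mc")
  }
  measured_kerma_mGy / simulated_kerma_per_history
}

#' Convert TLD-material dose to dose in air
#'
#' Multiplies the Monte Carlo dose scored in the TLD material by the
#' spectrum-averaged `(muen/rho)` air-to-TLD ratio evaluated on the
#' depth-hardened spectrum.
#'
#' @param d_mc dose (any scale) scored in TLD material.
#' @param hardened_spectrum spectrum at the tally depth.
#' @export
dose_to_air <- function(d_mc, hardened_spectrum) {
  d_mc * spectrum_avg_muen_ratio(hardened_spectrum, material_air(),
                                 material_tld())
}

#' Simulate a 2D dose map
#'
#' Replaces a thin layer at the requested depth with TLD material
#' (mirroring a radiochromic film) spanning the given lateral extent,
#' and scores a pixelized dose map with per-pixel history-by-history
#' uncertainty. The layer may overhang the phantom footprint, as a
#' physical film does; its depth must lie inside the phantom.
#'
#' @param phantom a `voxel_phantom`.
#' @param spectrum an `xray_spectrum`.
#' @param depth_cm depth of the layer top below the entrance surface.
#' @param n histories.
#' @param seed mandatory integer seed.
#' @param pitch_mm map pixel pitch.
#' @param size_mm layer extent `c(width_x, length_y)` (mm).
#' @param thickness_mm layer thickness.
#' @param ... further arguments passed to [run_mc()].
#' @return An `mc_result` with a `map` element.
#' @export
score_dose_map <- function(phantom, spectrum, depth_cm, n, seed,
                           pitch_mm = 1, size_mm = c(200, 120),
                           thickness_mm = 0.38, ...) {
  tmm <- phantom$thickness_cm * 10
  z_hi <- tmm - depth_cm * 10
  z_lo <- z_hi - thickness_mm
  if (z_lo < 0 || z_hi > tmm) {
    abort("map layer outside the phantom thickness",
          class = "mammodose_phantom_geometry")
  }
  map <- list(z_lo = z_lo, z_hi = z_hi, x_lo = -size_mm[1] / 2, y_lo = 0,
              pitch_mm = pitch_mm,
              nx = round(size_mm[1] / pitch_mm),
              ny = round(size_mm[2] / pitch_mm))
  run_mc(phantom, spectrum, n = n, seed = seed, map = map, ...)
}
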