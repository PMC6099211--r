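## Polyenergetic mammographic x-ray spectrum: Kramers-law generation,
## filtration, air kerma, half-value layer, filter tuning against a
## measured attenuation curve or a target HVL, and spectrum-averaged
## mass energy-absorption coefficient ratios.

# 1 keV per gram expressed in mGy
.KEV_PER_G_TO_MGY <- 1.602176634e-10

.new_spectrum <- function(energy_keV, fluence, bin_keV, kvp) {
  stopifnot(length(energy_keV) == length(fluence), all(fluence >= 0))
  structure(
    list(energy_keV = energy_keV, fluence = fluence,
         bin_keV = bin_keV, kvp = kvp),
    class = "xray_spectrum"
  )
}

#' @export
print.xray_spectrum <- function(x, ...) {
  cat(sprintf(
    "<xray_spectrum> %g kVp, %d bins of %g keV, mean energy %.2f keV\n",
    x$kvp, length(x$energy_keV), x$bin_keV, mean_energy(x)))
  invisible(x)
}

#' Spectrum as a tibble
#'
#' @param x an `xray_spectrum`.
#' @method as_tibble xray_spectrum
#' @param ... unused.
#' @return Tibble with bin center energy (keV), relative photon fluence
#'   per bin, and differential energy fluence `psi_E` (fluence times
#'   energy, per bin).
#' @export
as_tibble.xray_spectrum <- function(x, ...) {
  tibble(energy_keV = x$energy_keV, fluence = x$fluence,
         psi_E = x$fluence * x$energy_keV)
}

#' Model a tungsten-anode bremsstrahlung spectrum
#'
#' Kramers-law thick-target bremsstrahlung (`N(E) proportional to
#' (kVp - E)/E`) filtered by the tube's inherent beryllium window, binned
#' on a regular grid up to the tube potential and normalized to unit
#' total photon fluence. Characteristic tungsten lines are omitted: at
#' mammographic tube potentials (below ~69.5 kV) the K lines are not
#' excited, and the L lines are assumed absorbed by the window and
#' external filtration. The default 0.25 keV bin resolves the rhodium
#' K-edge step at 23.22 keV.
#'
#' @param kvp tube potential in kV (20-49).
#' @param bin_keV energy bin width in keV.
#' @param inherent_be_mm inherent beryllium window thickness in mm.
#' @param emin_keV lowest tabulated photon energy.
#' @return An `xray_spectrum` (photon fluence per bin, relative).
#' @examples
#' s <- kramers_spectrum(28)
#' first_hvl(attenuate_spectrum(s, material_rhodium(), 0.050))
#' @export
kramers_spectrum <- function(kvp = 28, bin_keV = 0.25, inherent_be_mm = 0.8,
                             emin_keV = 1) {
  if (!is.numeric(kvp) || kvp <= 0) {
    abort("kvp must be positive", class = "mammodose_invalid_spectrum")
  }
  if (kvp < 20 || kvp > 49) {
    abort("kvp outside supported 20-49 kV range",
          class = "mammodose_invalid_spectrum")
  }
  if (bin_keV <= 0) {
    abort("bin_keV must be > 0", class = "mammodose_invalid_spectrum")
  }
  centers <- seq(emin_keV + bin_keV / 2, kvp, by = bin_keV)
  centers <- centers[centers < kvp]
  n <- (kvp - centers) / centers
  s <- .new_spectrum(centers, n / sum(n), bin_keV, kvp)
  if (inherent_be_mm > 0) {
    s <- attenuate_spectrum(s, material_beryllium(), inherent_be_mm)
    s$fluence <- s$fluence / sum(s$fluence)
  }
  s
}

#' Attenuate a spectrum through a uniform absorber
#'
#' Per-bin Beer-Lambert attenuation `exp(-mu/rho * rho * t)`. Used both
#' for tube filtration and to produce the depth-hardened spectra seen at
#' 1-4 cm inside phantom material.
#'
#' @param spectrum an `xray_spectrum`.
#' @param material absorber `material`.
#' @param thickness_mm absorber thickness in mm (>= 0).
#' @return The attenuated `xray_spectrum` (fluence scale preserved).
#' @export
attenuate_spectrum <- function(spectrum, material, thickness_mm) {
  stopifnot(inherits(spectrum, "xray_spectrum"))
  if (thickness_mm < 0) {
    abort("thickness must be >= 0", class = "mammodose_invalid_spectrum")
  }
  if (thickness_mm == 0) {
    return(spectrum)
  }
  mu <- mu_over_rho(material, spectrum$energy_keV) * material$density
  spectrum$fluence <- spectrum$fluence * exp(-mu * thickness_mm / 10)
  spectrum
}

#' Mean energy of a spectrum
#'
#' Photon-fluence-weighted mean energy in keV.
#' @param spectrum an `xray_spectrum`.
#' @export
mean_energy <- function(spectrum) {
  stopifnot(inherits(spectrum, "xray_spectrum"))
  sum(spectrum$fluence * spectrum$energy_keV) / sum(spectrum$fluence)
}

#' Air kerma of a spectrum
#'
#' `K = sum Phi(E) E (muen/rho)_air(E)`, with the fluence interpreted as
#' photons/cm^2 after applying `fluence_scale`. Returns mGy.
#'
#' @param spectrum an `xray_spectrum`.
#' @param fluence_scale multiplies the stored relative fluence to give
#'   absolute photons/cm^2.
#' @export
air_kerma <- function(spectrum, fluence_scale = 1) {
  stopifnot(inherits(spectrum, "xray_spectrum"))
  if (length(spectrum$fluence) == 0L) {
    abort("empty spectrum", class = "mammodose_invalid_spectrum")
  }
  air <- material_air()
  muen <- muen_over_rho(air, spectrum$energy_keV)
  # photons/cm^2 * keV * cm^2/g = keV/g; 1 keV/g = 1.602e-10 mGy
  sum(fluence_scale * spectrum$fluence * spectrum$energy_keV * muen) *
    .KEV_PER_G_TO_MGY
}

#' First half-value layer
#'
#' Absorber thickness halving the air kerma, found by bisection on the
#' (strictly monotone) kerma transmission curve; tolerance 1e-4 mm.
#'
#' @param spectrum an `xray_spectrum`.
#' @param absorber absorbing `material` (high-purity aluminum by default).
#' @param bracket search interval in mm.
#' @return Thickness in mm.
#' @export
first_hvl <- function(spectrum, absorber = material_aluminum(),
                      bracket = c(0.01, 5)) {
  k0 <- air_kerma(spectrum)
  if (k0 <= 0) {
    abort("spectrum carries no kerma", class = "mammodose_invalid_spectrum")
  }
  f <- function(t) {
    air_kerma(attenuate_spectrum(spectrum, absorber, t)) / k0 - 0.5
  }
  if (f(bracket[1]) < 0 || f(bracket[2]) > 0) {
    abort("HVL not bracketed by search interval",
          class = "mammodose_hvl_bracket")
  }
  uniroot(f, bracket, tol = 1e-4)$root
}

#' Transmission curve through an absorber
#'
#' Air-kerma transmission fraction for each absorber thickness; the
#' simulated counterpart of an ionization-chamber attenuation-curve
#' measurement.
#'
#' @param spectrum an `xray_spectrum`.
#' @param absorber absorbing `material`.
#' @param thickness_mm vector of thicknesses (mm).
#' @return Tibble with `thickness_mm` and `transmission`.
#' @export
transmission_curve <- function(spectrum, absorber, thickness_mm) {
  k0 <- air_kerma(spectrum)
  tr <- vapply(thickness_mm, function(t) {
    air_kerma(attenuate_spectrum(spectrum, absorber, t)) / k0
  }, numeric(1))
  tibble(thickness_mm = thickness_mm, transmission = tr)
}

#' Tune the external filter thickness
#'
#' Adjusts the thickness of the external filter (rhodium for a W/Rh
#' beam) so that the modelled beam reproduces either a measured aluminum
#' attenuation curve (least-squares on the transmission residuals) or a
#' target first HVL. This mirrors how the clinical beam quality is
#' transferred onto the modelled spectrum.
#'
#' @param spectrum unfiltered `xray_spectrum` (tube + inherent window).
#' @param filter_material the external filter `material`.
#' @param target_hvl_mm target first HVL in mm Al, or `NULL`.
#' @param attenuation data frame with `thickness_mm` and `transmission`
#'   columns (measured Al attenuation curve), or `NULL`.
#' @param bracket filter-thickness search interval in mm.
#' @param absorber absorber used for the HVL / attenuation curve.
#' @return List with `thickness_mm`, achieved `hvl_mm`, and `residual`
#'   (sum of squared transmission residuals, curve targets only).
#' @export
tune_filter <- function(spectrum, filter_material = material_rhodium(),
                        target_hvl_mm = NULL, attenuation = NULL,
                        bracket = c(0.001, 0.2),
                        absorber = material_aluminum()) {
  if (is.null(target_hvl_mm) && is.null(attenuation)) {
    abort("supply target_hvl_mm or an attenuation curve",
          class = "mammodose_tune_target")
  }
  filtered <- function(t) attenuate_spectrum(spectrum, filter_material, t)
  if (!is.null(target_hvl_mm)) {
    f <- function(t) first_hvl(filtered(t), absorber) - target_hvl_mm
    lo <- f(bracket[1]); hi <- f(bracket[2])
    if (sign(lo) == sign(hi)) {
      abort(sprintf(
        "target HVL %.3f mm not reachable in bracket [%g, %g] mm (residuals %.4f / %.4f)",
        target_hvl_mm, bracket[1], bracket[2], lo, hi),
        class = "mammodose_tune_bracket")
    }
    t_opt <- uniroot(f, bracket, tol = 1e-6)$root
    res <- abs(f(t_opt))
  } else {
    if (nrow(attenuation) < 1) {
      abort("attenuation curve needs at least one point",
            class = "mammodose_tune_target")
    }
    if (nrow(attenuation) == 1 && attenuation$transmission[1] >= 1) {
      abort("degenerate attenuation target (single normalized point)",
            class = "mammodose_tune_target")
    }
    obj <- function(t) {
      pred <- transmission_curve(filtered(t), absorber,
                                 attenuation$thickness_mm)$transmission
      sum((pred - attenuation$transmission)^2)
    }
    opt <- optimize(obj, bracket, tol = 1e-7)
    # reject flat objectives (e.g. monoenergetic input, normalized point)
    spread <- abs(obj(bracket[1]) - obj(bracket[2]))
    if (spread < 1e-12 && opt$objective > 1e-10) {
      abort("objective is flat in filter thickness; degenerate target",
            class = "mammodose_tune_target")
    }
    t_opt <- opt$minimum
    res <- opt$objective
  }
  list(thickness_mm = t_opt, hvl_mm = first_hvl(filtered(t_opt), absorber),
       residual = res)
}

#' Spectrum-averaged mass energy-absorption coefficient ratio
#'
#' Ratio of the energy-fluence-weighted average `muen/rho` of two
#' materials, `(1/psi) integral (muen/rho)(E) psi_E dE` evaluated for the
#' numerator and denominator materials on the supplied (typically
#' depth-hardened) spectrum.
#'
#' @param spectrum an `xray_spectrum`, already hardened to the depth of
#'   interest where applicable.
#' @param mat_num numerator `material` (e.g. dry air).
#' @param mat_den denominator `material` (e.g. the TLD material).
#' @return Dimensionless ratio.
#' @export
spectrum_avg_muen_ratio <- function(spectrum, mat_num, mat_den) {
  stopifnot(inherits(spectrum, "xray_spectrum"))
  psi <- spectrum$fluence * spectrum$energy_keV
  if (sum(psi) <= 0) {
    abort("zero integral energy fluence", class = "mammodose_invalid_spectrum")
  }
  num <- sum(psi * muen_over_rho(mat_num, spectrum$energy_keV))
  den <- sum(psi * muen_over_rho(mat_den, spectrum$energy_keV))
  num / den
}

#' Read / write spectrum TSV
#'
#' Two tab-separated columns (bin-center energy in keV, relative photon
#' fluence); `#` starts a comment.
#'
#' @param path file path.
#' @param kvp tube potential; inferred as the top tabulated energy when
#'   omitted on read.
#' @export
read_spectrum <- function(path, kvp = NULL) {
  tab <- utils::read.delim(path, comment.char = "#", header = TRUE)
  if (ncol(tab) < 2) {
    abort("spectrum TSV needs two columns", class = "mammodose_format")
  }
  e <- tab[[1]]
  bw <- if (length(e) > 1) stats::median(diff(e)) else 1
  .new_spectrum(e, tab[[2]], bw, kvp %||% max(e) + bw / 2)
}

#' @rdname read_spectrum
#' @param spectrum an `xray_spectrum`.
#' @export
write_spectrum <- function(spectrum, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# x-ray spectrum, %g kVp", spectrum$kvp), con)
  writeLines("E_keV\tfluence", con)
  utils::write.table(
    data.frame(E_keV = spectrum$energy_keV, fluence = spectrum$fluence),
    con, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
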