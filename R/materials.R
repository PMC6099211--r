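## Elemental photon-interaction data and material construction.
##
## The package bundles a fixed snapshot of elemental mass attenuation
## (total + photoelectric/coherent/incoherent partials) and mass
## energy-absorption coefficients on a 1-40 keV grid (see
## inst/extdata/xsec/ and data-raw/make_xsec_tables.py for how the
## snapshot was computed and harmonized against standard air/water/Al
## reference values). Materials are mixtures of these elements; mixture
## coefficients follow the mass-weighted additivity rule with log-log
## interpolation between grid energies.

# atomic masses (g/mol) for the bundled element set
.ATOMIC_MASS <- c(
  H = 1.00794, Li = 6.941, Be = 9.012182, C = 12.0107, N = 14.0067,
  O = 15.9994, F = 18.9984032, Na = 22.98977, Mg = 24.305, Al = 26.981539,
  P = 30.973761, S = 32.065, Cl = 35.453, Ar = 39.948, K = 39.0983,
  Ca = 40.078, Cu = 63.546, Rh = 102.9055, W = 183.84
)

.element_data <- function(symbol) {
  key <- paste0("el_", symbol)
  if (!is.null(.mammodose_cache[[key]])) {
    return(.mammodose_cache[[key]])
  }
  if (!symbol %in% names(.ATOMIC_MASS)) {
    abort(sprintf("no bundled cross-section data for element '%s'", symbol),
          class = "mammodose_unknown_element")
  }
  path <- system.file("extdata", "xsec", paste0(symbol, ".tsv"),
                      package = "mammodose", mustWork = TRUE)
  tab <- utils::read.delim(path, comment.char = "#")
  stopifnot(all(diff(tab$E_keV) > 0), all(tab$mu_rho > 0))
  dat <- list(
    symbol = symbol,
    E = tab$E_keV,
    logE = log(tab$E_keV),
    log_mu = log(tab$mu_rho),
    log_pe = log(pmax(tab$mu_rho_pe, 1e-12)),
    log_coh = log(tab$mu_rho_coh),
    log_incoh = log(tab$mu_rho_incoh),
    log_muen = log(tab$muen_rho)
  )
  .mammodose_cache[[key]] <- dat
  dat
}

# log-log linear interpolation, strict range check
.interp_loglog <- function(logx, logy, energy_keV) {
  rng <- range(exp(logx))
  if (any(energy_keV < rng[1] - 1e-9 | energy_keV > rng[2] + 1e-9)) {
    abort(sprintf(
      "energy outside tabulated range [%.3g, %.3g] keV", rng[1], rng[2]),
      class = "mammodose_energy_range")
  }
  exp(approx(logx, logy, xout = log(energy_keV), rule = 1)$y)
}

.element_coef <- function(symbol, energy_keV,
                          which = c("mu", "muen", "pe", "coh", "incoh")) {
  which <- match.arg(which)
  d <- .element_data(symbol)
  col <- switch(which, mu = d$log_mu, muen = d$log_muen, pe = d$log_pe,
                coh = d$log_coh, incoh = d$log_incoh)
  .interp_loglog(d$logE, col, energy_keV)
}

# split a chemical formula (e.g. "LiF", "H2O", "C10H8O4") into element
# mass fractions
.formula_mass_fractions <- function(formula) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", formula)
  parts <- regmatches(formula, m)[[1]]
  if (length(parts) == 0L || paste(parts, collapse = "") != formula) {
    abort(sprintf("cannot parse chemical formula '%s'", formula),
          class = "mammodose_bad_formula")
  }
  syms <- sub("[0-9.]*$", "", parts)
  cnts <- as.numeric(sub("^[A-Za-z]+", "", parts))
  cnts[is.na(cnts)] <- 1
  unknown <- setdiff(syms, names(.ATOMIC_MASS))
  if (length(unknown)) {
    abort(sprintf("no data for element(s): %s", paste(unknown, collapse = ", ")),
          class = "mammodose_unknown_element")
  }
  masses <- .ATOMIC_MASS[syms] * cnts
  tapply(masses / sum(masses), syms, sum)
}

#' Define a material from mass fractions
#'
#' Builds a material from a named composition vector and a density.
#' Composition names may be element symbols (`"O"`) or simple chemical
#' formulas (`"LiF"`, `"C10H8O4"`); formula entries are expanded to their
#' constituent elements by stoichiometric mass ratio, so total mass is
#' preserved. Fractions must sum to 1 within `tol` and are renormalized
#' exactly.
#'
#' @param name character label for the material.
#' @param composition named numeric vector of mass fractions.
#' @param density mass density in g/cm^3.
#' @param tol allowed deviation of the fraction sum from 1.
#' @param glandular_fraction mass fraction of the material that counts as
#'   glandular tissue when computing phantom glandularity (1 for
#'   glandular tissue, 0 for adipose/skin/other, intermediate for
#'   glandular/adipose mixtures).
#' @return An object of class `material` with elements `name`, `density`
#'   (g/cm^3), `mass_fractions` (named vector over element symbols) and
#'   `glandular_fraction`.
#' @examples
#' tld <- make_material("TLD-100H",
#'   c(LiF = 0.995, Mg = 0.002, Cu = 0.00004, P = 0.00296), density = 2.48)
#' mu_over_rho(tld, 20)
#' @export
make_material <- function(name, composition, density, tol = 1e-3,
                          glandular_fraction = 0) {
  if (!is.numeric(composition) || is.null(names(composition))) {
    abort("composition must be a named numeric vector",
          class = "mammodose_invalid_composition")
  }
  if (any(composition < 0)) {
    abort("mass fractions must be nonnegative",
          class = "mammodose_invalid_composition")
  }
  if (abs(sum(composition) - 1) > tol) {
    abort(sprintf("mass fractions sum to %.6g, not 1", sum(composition)),
          class = "mammodose_invalid_composition")
  }
  if (!is.numeric(density) || density <= 0) {
    abort("density must be > 0", class = "mammodose_invalid_composition")
  }
  frac <- numeric(0)
  for (i in seq_along(composition)) {
    nm <- names(composition)[i]
    part <- if (nm %in% names(.ATOMIC_MASS)) {
      setNames(composition[[i]], nm)
    } else {
      .formula_mass_fractions(nm) * composition[[i]]
    }
    for (s in names(part)) {
      frac[s] <- (if (s %in% names(frac)) frac[[s]] else 0) + part[[s]]
    }
  }
  frac <- frac / sum(frac)
  structure(
    list(name = name, density = density, mass_fractions = frac,
         glandular_fraction = glandular_fraction),
    class = "material"
  )
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("<material> %s  (rho = %.4g g/cm^3)\n", x$name, x$density))
  comp <- paste(sprintf("%s %.4g", names(x$mass_fractions), x$mass_fractions),
                collapse = ", ")
  cat(" ", comp, "\n")
  invisible(x)
}

#' Mix materials by mass
#'
#' Elemental fractions of the mixture are mass-weighted sums of the
#' component fractions; the mixture density follows the inverse-volume
#' rule `1 / sum(w_i / rho_i)` (component volumes add).
#'
#' @param materials list of `material` objects.
#' @param weights mass weights, summing to 1.
#' @param name optional label for the mixture.
#' @return A `material`.
#' @examples
#' m <- mix_by_mass(list(material_glandular(), material_adipose()),
#'                  c(0.109, 0.891))
#' @export
mix_by_mass <- function(materials, weights, name = NULL) {
  if (length(materials) == 0L) {
    abort("no materials to mix", class = "mammodose_invalid_composition")
  }
  stopifnot(length(materials) == length(weights))
  if (abs(sum(weights) - 1) > 1e-9) {
    abort("mixture weights must sum to 1",
          class = "mammodose_invalid_composition")
  }
  frac <- numeric(0)
  for (i in seq_along(materials)) {
    mf <- materials[[i]]$mass_fractions * weights[i]
    for (s in names(mf)) {
      frac[s] <- (if (s %in% names(frac)) frac[[s]] else 0) + mf[[s]]
    }
  }
  dens <- 1 / sum(weights / vapply(materials, `[[`, numeric(1), "density"))
  gf <- sum(weights * vapply(materials, function(m) {
    m$glandular_fraction %||% 0
  }, numeric(1)))
  if (is.null(name)) {
    name <- paste(vapply(materials, `[[`, character(1), "name"),
                  collapse = "+")
  }
  structure(
    list(name = name, density = dens, mass_fractions = frac / sum(frac),
         glandular_fraction = gf),
    class = "material"
  )
}

.material_coef <- function(material, energy_keV, which) {
  stopifnot(inherits(material, "material"))
  out <- 0
  for (s in names(material$mass_fractions)) {
    out <- out + material$mass_fractions[[s]] *
      .element_coef(s, energy_keV, which)
  }
  out
}

#' Mass attenuation and mass energy-absorption coefficients
#'
#' Mixture-rule coefficients `sum_i w_i (mu/rho)_i(E)` with log-log
#' interpolation between tabulated grid energies. Energies must lie
#' within the bundled 1-40 keV tables; no extrapolation is performed.
#'
#' @param material a `material`.
#' @param energy_keV photon energies in keV (vectorized).
#' @return Coefficient(s) in cm^2/g.
#' @export
mu_over_rho <- function(material, energy_keV) {
  .material_coef(material, energy_keV, "mu")
}

#' @rdname mu_over_rho
#' @export
muen_over_rho <- function(material, energy_keV) {
  .material_coef(material, energy_keV, "muen")
}

## ---- stock materials ------------------------------------------------------

#' Stock materials
#'
#' Materials used throughout the simulated mammography setup. Breast
#' tissue compositions (adipose, glandular) follow the Hammerstein
#' elemental analyses standard in breast dosimetry; skin follows ICRU-44.
#' The 50/50 breast material is the equal-mass glandular/adipose mixture
#' used for homogeneous slab phantoms. The TLD material is LiF:Mg,Cu,P
#' (99.5% LiF, 0.2% Mg, 0.004% Cu, 0.296% P by mass, 2.48 g/cm^3). Dry
#' air is the standard 4-component composition at sea level.
#'
#' @return A `material`.
#' @name stock-materials
NULL

#' @rdname stock-materials
#' @export
material_air <- function() {
  make_material("dry air",
    c(C = 0.000124, N = 0.755267, O = 0.231781, Ar = 0.012827),
    density = 1.205e-3)
}

#' @rdname stock-materials
#' @export
material_adipose <- function() {
  make_material("adipose",
    c(H = 0.112, C = 0.619, N = 0.017, O = 0.251, P = 0.001),
    density = 0.93)
}

#' @rdname stock-materials
#' @export
material_glandular <- function() {
  make_material("glandular",
    c(H = 0.102, C = 0.184, N = 0.032, O = 0.677, P = 0.005),
    density = 1.04, glandular_fraction = 1)
}

#' @rdname stock-materials
#' @export
material_skin <- function() {
  make_material("skin",
    c(H = 0.100, C = 0.204, N = 0.042, O = 0.645, Na = 0.002, P = 0.001,
      S = 0.002, Cl = 0.003, K = 0.001),
    density = 1.09)
}

#' @rdname stock-materials
#' @export
material_breast5050 <- function() {
  m <- mix_by_mass(list(material_glandular(), material_adipose()),
                   c(0.5, 0.5), name = "breast 50/50")
  m
}

#' @rdname stock-materials
#' @export
material_tld <- function() {
  make_material("LiF:Mg,Cu,P",
    c(LiF = 0.995, Mg = 0.002, Cu = 0.00004, P = 0.00296),
    density = 2.48)
}

#' @rdname stock-materials
#' @export
material_pet <- function() {
  make_material("PET", c(C10H8O4 = 1), density = 1.40)
}

#' @rdname stock-materials
#' @export
material_carbon_fiber <- function() {
  make_material("carbon fiber", c(C = 1), density = 1.70)
}

#' @rdname stock-materials
#' @export
material_aluminum <- function() {
  make_material("aluminum", c(Al = 1), density = 2.699)
}

#' @rdname stock-materials
#' @export
material_beryllium <- function() {
  make_material("beryllium", c(Be = 1), density = 1.848)
}

#' @rdname stock-materials
#' @export
material_rhodium <- function() {
  make_material("rhodium", c(Rh = 1), density = 12.41)
}
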