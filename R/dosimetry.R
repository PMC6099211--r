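## Dosimeter calibration models and uncertainty propagation.
##
## Three dosimeter technologies are modelled: radiochromic (GafChromic)
## film read out as net reflectance change, LiF:Mg,Cu,P TLD chips read
## in nC, and MOSFET dosimeters read as threshold-voltage shifts. All
## calibrations are depth-specific: beam hardening changes the local
## spectrum with depth and all three technologies are energy dependent,
## so a calibration acquired at one depth is refused at another unless
## explicitly overridden.

.check_depth <- function(calib, depth_cm, override) {
  if (is.null(depth_cm) || is.null(calib$depth_cm)) {
    return(invisible(TRUE))
  }
  if (!isTRUE(override) && abs(depth_cm - calib$depth_cm) > 1e-9) {
    abort(sprintf(
      "calibration is for depth %g cm but the measurement is at %g cm; beam hardening makes these incompatible (use override = TRUE to force)",
      calib$depth_cm, depth_cm), class = "mammodose_depth_mismatch")
  }
  invisible(TRUE)
}

#' Bundled depth-specific calibration tables
#'
#' Calibration constants for the three dosimeter technologies at each
#' phantom depth (film calibration-curve and uncertainty-model
#' coefficients; MOSFET calibration-factor ranges and TLD calibration
#' factors).
#'
#' @return A tibble.
#' @export
gaf_calibration_table <- function() {
  path <- system.file("extdata", "calibration", "gaf_calibration.csv",
                      package = "mammodose", mustWork = TRUE)
  as_tibble(utils::read.csv(path, comment.char = "#"))
}

#' @rdname gaf_calibration_table
#' @export
point_calibration_table <- function() {
  path <- system.file("extdata", "calibration", "point_calibration.csv",
                      package = "mammodose", mustWork = TRUE)
  as_tibble(utils::read.csv(path, comment.char = "#"))
}

#' GafChromic film calibration object
#'
#' Dose response `dose(x) = a + b x / ln(x)` for net reflectance change
#' `x` in (0, 1), valid over roughly 1-10 mGy, with the relative
#' combined-uncertainty model `u%(dose) = u_a + u_b exp(-dose/u_c)`.
#'
#' @param a,b calibration-curve coefficients (mGy).
#' @param unc `c(a, b, c)` of the uncertainty model (%, %, mGy).
#' @param depth_cm depth the calibration was acquired at.
#' @return A `gaf_calib` object.
#' @export
gaf_calib <- function(a, b, unc = NULL, depth_cm = NULL) {
  structure(list(a = a, b = b, unc = unc, depth_cm = depth_cm),
            class = "gaf_calib")
}

#' @rdname gaf_calib
#' @param depth depth row to take from the bundled table.
#' @export
gaf_calib_at_depth <- function(depth) {
  tab <- gaf_calibration_table()
  row <- tab[abs(tab$depth_cm - depth) < 1e-9, ]
  if (nrow(row) != 1) {
    abort(sprintf("no bundled film calibration at depth %g cm", depth),
          class = "mammodose_depth_mismatch")
  }
  gaf_calib(row$a, row$b, unc = c(row$unc_a, row$unc_b, row$unc_c),
            depth_cm = row$depth_cm)
}

#' Fit a GafChromic calibration curve
#'
#' Least squares of `dose = a + b x/ln(x)` (linear in `a`, `b`) on
#' (net reflectance change, air kerma) calibration pairs.
#'
#' @param pairs data frame with columns `net_dR` (in (0,1)) and
#'   `kerma_mGy`.
#' @param depth_cm depth the calibration beam was hardened to.
#' @return A `gaf_calib` with `residuals` and `r.squared` attached.
#' @export
fit_gaf_calibration <- function(pairs, depth_cm = NULL) {
  stopifnot(all(c("net_dR", "kerma_mGy") %in% names(pairs)))
  x <- pairs$net_dR
  if (any(x <= 0) || any(x >= 1)) {
    abort("net_dR must lie strictly inside (0, 1); ln(1) = 0 is singular",
          class = "mammodose_gaf_domain")
  }
  if (nrow(pairs) < 3) {
    abort("need at least 3 calibration pairs", class = "mammodose_gaf_fit")
  }
  if (anyDuplicated(x) && length(unique(pairs$kerma_mGy)) > 1) {
    warn("duplicated net_dR values with differing kerma: design is degenerate")
  }
  g <- x / log(x)
  fit <- lm(pairs$kerma_mGy ~ g)
  out <- gaf_calib(unname(coef(fit)[1]), unname(coef(fit)[2]),
                   depth_cm = depth_cm)
  out$residuals <- unname(stats::residuals(fit))
  ss_tot <- sum((pairs$kerma_mGy - mean(pairs$kerma_mGy))^2)
  out$r.squared <- 1 - sum(out$residuals^2) / ss_tot
  out
}

#' @method tidy gaf_calib
#' @export
tidy.gaf_calib <- function(x, ...) {
  tibble(term = c("a", "b"), estimate = c(x$a, x$b))
}

#' @method glance gaf_calib
#' @export
glance.gaf_calib <- function(x, ...) {
  tibble(r.squared = x$r.squared %||% NA_real_,
         sigma = if (is.null(x$residuals)) NA_real_ else
           stats::sd(x$residuals),
         depth_cm = x$depth_cm %||% NA_real_)
}

#' Film dose and uncertainty
#'
#' `gaf_dose()` maps a net reflectance change to dose through the
#' calibration curve; `gaf_uncertainty()` evaluates the relative
#' combined standard uncertainty (k = 1, percent) at a given dose.
#'
#' @param net_dR net reflectance change(s), strictly inside (0, 1).
#' @param calib a `gaf_calib`.
#' @param depth_cm depth of the measurement (checked against the
#'   calibration depth).
#' @param override apply the calibration across depths anyway?
#' @export
gaf_dose <- function(net_dR, calib, depth_cm = NULL, override = FALSE) {
  .check_depth(calib, depth_cm, override)
  if (any(net_dR <= 0) || any(net_dR >= 1)) {
    abort("net_dR must lie strictly inside (0, 1)",
          class = "mammodose_gaf_domain")
  }
  calib$a + calib$b * net_dR / log(net_dR)
}

#' @rdname gaf_dose
#' @param dose_mGy dose at which to evaluate the uncertainty model.
#' @export
gaf_uncertainty <- function(dose_mGy, calib, depth_cm = NULL,
                            override = FALSE) {
  .check_depth(calib, depth_cm, override)
  if (is.null(calib$unc)) {
    abort("calibration has no uncertainty model",
          class = "mammodose_gaf_domain")
  }
  u <- calib$unc
  u[1] + u[2] * exp(-dose_mGy / u[3])
}

#' TLD calibration and dose
#'
#' Chip dose `D_i = Q_i K_calib / S_i` from the reading `Q_i` (nC), the
#' calibration factor `K_calib` (mGy/nC) and the chip-specific
#' dimensionless sensitivity `S_i`; a position dose is the mean over the
#' (typically three) chips at that position.
#'
#' @param K_calib calibration factor (mGy/nC).
#' @param S chip sensitivity factor(s).
#' @param depth_cm calibration depth.
#' @export
tld_calib <- function(K_calib, S = 1, depth_cm = NULL) {
  if (K_calib <= 0 || any(S <= 0)) {
    abort("K_calib and S must be > 0", class = "mammodose_calib_domain")
  }
  structure(list(K_calib = K_calib, S = S, depth_cm = depth_cm),
            class = "tld_calib")
}

#' @rdname tld_calib
#' @param Q_nC chip reading(s) in nC.
#' @param calib a `tld_calib`.
#' @param override apply the calibration across depths anyway?
#' @return `tld_dose()`: per-chip doses in mGy; average chips with
#'   `mean()` for the position dose.
#' @export
tld_dose <- function(Q_nC, calib, depth_cm = NULL, override = FALSE) {
  .check_depth(calib, depth_cm, override)
  s <- rep_len(calib$S, length(Q_nC))
  Q_nC * calib$K_calib / s
}

#' MOSFET calibration and dose
#'
#' The position dose is the mean of the exposure ratios
#' `deltaV / CF` over the (typically three) repeated exposures.
#'
#' @param CF calibration factor (mV/mGy) of the dosimeter.
#' @param depth_cm calibration depth.
#' @export
mosfet_calib <- function(CF, depth_cm = NULL) {
  if (CF <= 0) abort("CF must be > 0", class = "mammodose_calib_domain")
  structure(list(CF = CF, depth_cm = depth_cm), class = "mosfet_calib")
}

#' @rdname mosfet_calib
#' @param delta_V_mV voltage shifts (mV) of the repeated exposures.
#' @param calib a `mosfet_calib`.
#' @param override apply the calibration across depths anyway?
#' @export
mosfet_dose <- function(delta_V_mV, calib, depth_cm = NULL,
                        override = FALSE) {
  .check_depth(calib, depth_cm, override)
  if (any(delta_V_mV < 0)) {
    warn("negative voltage shift: possible signal inversion")
  }
  mean(delta_V_mV / calib$CF)
}

#' Combine uncertainty components in quadrature
#'
#' Combined standard uncertainty (k = 1) of Type A components (already
#' standard uncertainties) and Type B components specified as rectangular
#' half-widths, converted via `u = half_width / sqrt(3)` before the
#' quadrature sum. All values are relative (percent).
#'
#' @param components either a numeric vector (all Type A) or a data
#'   frame with columns `value` and `type` (`"A"` or `"B"`); Type B rows
#'   give the rectangular half-width in `value`.
#' @return Combined relative standard uncertainty (percent).
#' @examples
#' combine_uncertainty(c(3, 4))               # 5
#' combine_uncertainty(data.frame(value = sqrt(3), type = "B"))  # 1
#' @export
combine_uncertainty <- function(components) {
  if (is.data.frame(components)) {
    stopifnot(all(c("value", "type") %in% names(components)))
    if (nrow(components) == 0L) {
      abort("need at least one component", class = "mammodose_unc")
    }
    u <- ifelse(components$type == "B",
                components$value / sqrt(3), components$value)
  } else {
    if (length(components) == 0L) {
      abort("need at least one component", class = "mammodose_unc")
    }
    u <- components
  }
  if (any(u < 0)) abort("components must be >= 0", class = "mammodose_unc")
  sqrt(sum(u^2))
}

# invert the film calibration: find x in (0,1) with dose(x) = dose;
# doses at or below the curve's zero-signal limit `a` have no readable
# reflectance change and come back NA
.gaf_invert <- function(dose_mGy, calib) {
  vapply(dose_mGy, function(d) {
    if (d <= calib$a) {
      warn(sprintf("dose %.3g mGy below the film's zero-signal limit %.3g",
                   d, calib$a))
      return(NA_real_)
    }
    uniroot(function(x) calib$a + calib$b * x / log(x) - d,
            c(1e-9, 1 - 1e-9), tol = 1e-12)$root
  }, numeric(1))
}

#' Generate synthetic dosimeter readings
#'
#' Emulates dosimeter data for end-to-end tests: true doses are
#' perturbed by Gaussian relative noise at the requested scale and
#' pushed backwards through the calibration, so reconstructing the dose
#' from the readings is unbiased with RMSE equal to the noise level.
#'
#' @param true_dose_mGy vector of true doses.
#' @param calib a `gaf_calib`, `tld_calib` or `mosfet_calib`.
#' @param noise_pct relative Gaussian noise (percent).
#' @param seed mandatory integer seed.
#' @return Tibble with `true_dose_mGy` and the technology's reading
#'   (`net_dR`, `Q_nC`, or `delta_V_mV`).
#' @export
synth_readings <- function(true_dose_mGy, calib, noise_pct = 0, seed) {
  if (missing(seed)) abort("seed is mandatory", class = "mammodose_seed")
  if (inherits(calib, "gaf_calib") &&
      (any(true_dose_mGy < 1) || any(true_dose_mGy > 10))) {
    warn("dose outside the 1-10 mGy film calibration range")
  }
  noisy <- .with_seed(seed, {
    true_dose_mGy * (1 + rnorm(length(true_dose_mGy), 0, noise_pct / 100))
  })
  if (inherits(calib, "gaf_calib")) {
    tibble(true_dose_mGy = true_dose_mGy, net_dR = .gaf_invert(noisy, calib))
  } else if (inherits(calib, "tld_calib")) {
    s <- rep_len(calib$S, length(noisy))
    tibble(true_dose_mGy = true_dose_mGy,
           Q_nC = noisy * s / calib$K_calib)
  } else if (inherits(calib, "mosfet_calib")) {
    tibble(true_dose_mGy = true_dose_mGy, delta_V_mV = noisy * calib$CF)
  } else {
    abort("unknown calibration type", class = "mammodose_calib_domain")
  }
}
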