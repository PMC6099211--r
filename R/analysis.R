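## Depth-dose summaries, average glandular dose, dose-value histograms
## and measurement-simulation agreement tests.

#' Depth-dose summary
#'
#' Per-depth mean, spread and count of the position doses, in a tidy
#' table ordered by depth.
#'
#' @param results data frame with columns `depth_cm`, `dose` (and
#'   optionally `position`).
#' @return A `depth_dose_table` tibble with `depth_cm`, `mean_dose`,
#'   `sd_dose`, `n`.
#' @export
depth_dose_summary <- function(results) {
  stopifnot(all(c("depth_cm", "dose") %in% names(results)))
  if (length(unique(results$depth_cm)) < 2) {
    abort("need at least two depths", class = "mammodose_analysis")
  }
  out <- results |>
    dplyr::group_by(.data$depth_cm) |>
    dplyr::summarise(mean_dose = mean(.data$dose),
                     sd_dose = stats::sd(.data$dose),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$depth_cm)
  class(out) <- c("depth_dose_table", class(out))
  out
}

#' Percent dose decrease between two depths
#'
#' `100 (1 - mean(d2)/mean(d1))`, e.g. the entrance-to-4 cm dose drop.
#'
#' @param summary a `depth_dose_table` (or any data frame with
#'   `depth_cm` and `mean_dose`).
#' @param d1,d2 the two depths (cm), `d1` shallower.
#' @return Percent decrease.
#' @export
percent_decrease <- function(summary, d1, d2) {
  pick <- function(d) {
    row <- summary[abs(summary$depth_cm - d) < 1e-9, ]
    if (nrow(row) != 1) {
      abort(sprintf("depth %g cm not present in the summary", d),
            class = "mammodose_analysis")
    }
    row$mean_dose
  }
  100 * (1 - pick(d2) / pick(d1))
}

#' Average glandular dose from a per-voxel deposition array
#'
#' Mass-weighted mean dose over the glandular tissue. In a voxel
#' labelled as pure glandular tissue all deposited energy belongs to the
#' glandular mass. In a voxel holding a homogeneous glandular/adipose
#' mixture, the deposited energy partitions between the two components
#' in proportion to their mass energy-absorption shares, so the
#' glandular energy fraction is
#' `G = w_g (muen/rho)_g / [w_g (muen/rho)_g + (1-w_g) (muen/rho)_a]`,
#' evaluated as a spectrum-weighted average on the supplied (ideally
#' depth-hardened) spectrum.
#'
#' @param phantom the `voxel_phantom` the simulation ran on.
#' @param voxel_keV per-voxel deposited energy (keV), as returned by
#'   [run_mc()] with `voxel_tally = TRUE`.
#' @param spectrum an `xray_spectrum` used to average the G factor;
#'   required when the phantom contains mixture voxels.
#' @return Average glandular dose in mGy per history (for an unscaled
#'   run).
#' @export
agd <- function(phantom, voxel_keV, spectrum = NULL) {
  stopifnot(all(dim(voxel_keV) == dim(phantom$labels)))
  v_cm3 <- (phantom$voxel_mm / 10)^3
  e_gland <- 0
  m_gland <- 0
  for (l in names(phantom$label_map)) {
    m <- phantom$label_map[[l]]
    gf <- m$glandular_fraction %||% 0
    if (gf <= 0) next
    if (gf < 1) {
      if (is.null(spectrum)) {
        abort(paste("phantom holds glandular/adipose mixture voxels;",
                    "supply the spectrum to average the G factor"),
              class = "mammodose_analysis")
      }
      psi <- spectrum$fluence * spectrum$energy_keV
      e <- spectrum$energy_keV
      g_share <- sum(psi * gf * muen_over_rho(material_glandular(), e)) /
        sum(psi * muen_over_rho(m, e))
    } else {
      g_share <- 1
    }
    sel <- phantom$labels == as.integer(l)
    e_gland <- e_gland + g_share * sum(voxel_keV[sel])
    m_gland <- m_gland + gf * sum(sel) * m$density * v_cm3
  }
  if (m_gland == 0) {
    abort("phantom has no glandular tissue", class = "mammodose_analysis")
  }
  e_gland / m_gland * 1.602176634e-10  # keV/g -> mGy
}

#' Three-region dose-value histogram
#'
#' Splits dose-map values at two thresholds (defaults 3 and 8 mGy) into
#' the regions characteristic of an in-phantom film exposure: below the
#' lower threshold (not directly irradiated), between the thresholds
#' (inside the phantom) and above the upper threshold (outside the
#' phantom, free-in-air). Also bins the full histogram, normalized to a
#' unit maximum.
#'
#' @param map_mGy numeric vector or matrix of dose values (mGy).
#' @param thresholds two ascending thresholds (mGy).
#' @param bin_mGy histogram bin width.
#' @return A `region_histogram`: list with `regions` tibble
#'   (region, n, fraction) and `histogram` tibble (mid, count,
#'   normalized).
#' @export
dose_histogram <- function(map_mGy, thresholds = c(3, 8), bin_mGy = 0.25) {
  v <- as.vector(map_mGy)
  v <- v[is.finite(v)]
  if (length(v) == 0L) {
    abort("empty dose map", class = "mammodose_analysis")
  }
  if (length(thresholds) != 2 || diff(thresholds) <= 0) {
    abort("thresholds must be two ascending values",
          class = "mammodose_analysis")
  }
  bin <- cut(v, c(-Inf, thresholds, Inf),
             labels = c("below", "within", "above"))
  counts <- as.integer(table(bin))
  regions <- tibble(
    region = c("below", "within", "above"),
    n = counts,
    fraction = counts / length(v)
  )
  breaks <- seq(0, max(v) + bin_mGy, by = bin_mGy)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  histogram <- tibble(mid = h$mids, count = h$counts,
                      normalized = h$counts / max(h$counts))
  structure(list(regions = regions, histogram = histogram,
                 thresholds = thresholds),
            class = "region_histogram")
}

#' @export
print.region_histogram <- function(x, ...) {
  cat(sprintf("<region_histogram> thresholds %g / %g mGy\n",
              x$thresholds[1], x$thresholds[2]))
  print(x$regions)
  invisible(x)
}

#' Measurement-simulation agreement test
#'
#' `z = |meas - sim| / sqrt(u_meas^2 + u_sim^2)`; the pair agrees at
#' coverage factor `k` when `z <= k` (k = 1 for one combined standard
#' uncertainty, k = 3 for a ~99% interval).
#'
#' @param meas,u_meas measured values and absolute standard
#'   uncertainties.
#' @param sim,u_sim simulated values and absolute standard
#'   uncertainties.
#' @param k coverage factor.
#' @return Tibble with `z` and `pass` per pair.
#' @export
agreement_check <- function(meas, u_meas, sim, u_sim, k = 1) {
  if (any(u_meas <= 0) || any(u_sim <= 0)) {
    abort("uncertainties must be > 0", class = "mammodose_analysis")
  }
  z <- abs(meas - sim) / sqrt(u_meas^2 + u_sim^2)
  tibble(meas = meas, sim = sim, z = z, pass = z <= k)
}
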