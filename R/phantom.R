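## Voxelized compressed-breast phantoms.
##
## Coordinates are right-handed with the origin at the chest-wall edge on
## the detector midline: x lateral (centered), y chest wall -> nipple,
## z upward from the support-table top. Voxel indices are 1-based in R;
## voxel [i,j,k] spans the half-open box
## origin + ([i-1,i) , [j-1,j) , [k-1,k)) * voxel_mm.

.new_phantom <- function(labels, voxel_mm, origin_mm, label_map,
                         thickness_cm) {
  stopifnot(length(dim(labels)) == 3, voxel_mm > 0)
  lbls <- sort(unique(as.integer(labels)))
  missing <- setdiff(as.character(lbls), names(label_map))
  if (length(missing)) {
    abort(paste("labels missing from label_map:",
                paste(missing, collapse = ", ")),
          class = "mammodose_phantom_labels")
  }
  structure(
    list(labels = labels, voxel_mm = voxel_mm, origin_mm = origin_mm,
         label_map = label_map, thickness_cm = thickness_cm),
    class = "voxel_phantom"
  )
}

#' @export
print.voxel_phantom <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf(
    "<voxel_phantom> %d x %d x %d voxels of %.4g mm, thickness %.3g cm\n",
    d[1], d[2], d[3], x$voxel_mm, x$thickness_cm))
  tabs <- table(x$labels)
  for (l in names(tabs)) {
    nm <- x$label_map[[l]]$name
    cat(sprintf("  label %s (%s): %d voxels\n", l, nm, tabs[[l]]))
  }
  invisible(x)
}

# voxel-center coordinate vectors
.voxel_centers <- function(phantom) {
  d <- dim(phantom$labels)
  v <- phantom$voxel_mm
  list(
    x = phantom$origin_mm[1] + (seq_len(d[1]) - 0.5) * v,
    y = phantom$origin_mm[2] + (seq_len(d[2]) - 0.5) * v,
    z = phantom$origin_mm[3] + (seq_len(d[3]) - 0.5) * v
  )
}

#' Homogeneous semicylindrical slab phantom
#'
#' A semicylinder of uniform tissue-equivalent material, flat face flush
#' with the chest-wall edge (y = 0), resting on the support table
#' (z = 0). Voxels outside the semicylinder are air.
#'
#' @param radius_mm semicylinder radius (mm).
#' @param thickness_cm compressed thickness (cm).
#' @param voxel_mm cubic voxel side (mm); the reference pitch is
#'   0.273 mm, coarser grids trade resolution for speed.
#' @param material the slab `material` (50/50 glandular/adipose default).
#' @return A `voxel_phantom` with labels 0 (air) and 1 (tissue).
#' @export
build_homogeneous <- function(radius_mm = 100, thickness_cm = 5,
                              voxel_mm = 0.273,
                              material = material_breast5050()) {
  if (thickness_cm <= 0 || radius_mm <= 0) {
    abort("radius and thickness must be > 0",
          class = "mammodose_phantom_geometry")
  }
  tmm <- thickness_cm * 10
  if (voxel_mm > min(radius_mm, tmm)) {
    abort("voxel larger than phantom", class = "mammodose_phantom_geometry")
  }
  nx <- ceiling(2 * radius_mm / voxel_mm)
  ny <- ceiling(radius_mm / voxel_mm)
  nz <- ceiling(tmm / voxel_mm)
  x <- -radius_mm + (seq_len(nx) - 0.5) * voxel_mm
  y <- (seq_len(ny) - 0.5) * voxel_mm
  mask <- outer(x^2, y^2, `+`) <= radius_mm^2
  labels <- array(0L, c(nx, ny, nz))
  labels[rep(mask, nz)] <- 1L
  .new_phantom(labels, voxel_mm, c(-radius_mm, 0, 0),
               list(`0` = material_air(), `1` = material),
               thickness_cm)
}

# restore RNG state after using a local seed
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv())
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Synthetic anthropomorphic breast phantom
#'
#' Generates a reproducible trinary (skin / adipose / glandular)
#' compressed-breast voxel volume: a semicylindrical outline with a
#' 1.5 mm skin shell on the curved surface and the top/bottom faces,
#' adipose background, and glandular tissue laid down as smoothed random
#' blobs concentrated toward the phantom center (both in-plane and at
#' mid-thickness, where fibroglandular tissue sits in a compressed
#' breast). The glandular voxel count is chosen so the achieved
#' glandular mass fraction matches `target_glandularity` exactly up to
#' voxel rounding.
#'
#' @param seed integer seed; the same seed reproduces the same labels.
#' @param thickness_cm compressed thickness (cm).
#' @param target_glandularity target glandular mass fraction (mass of
#'   glandular tissue over all tissue including skin).
#' @param radius_mm footprint radius (mm).
#' @param voxel_mm cubic voxel side (mm).
#' @param n_blobs number of Gaussian glandular blobs.
#' @param blob_sigma_mm range of blob standard deviations (mm).
#' @param z_spread standard deviation of the blob centers around
#'   mid-thickness, as a fraction of the thickness; controls how
#'   strongly the glandular tissue concentrates at mid-depth.
#' @param skin_mm skin shell thickness (mm).
#' @return A `voxel_phantom` with labels 0 air, 1 adipose, 2 glandular,
#'   3 skin.
#' @export
build_synthetic_breast <- function(seed, thickness_cm = 4.5,
                                   target_glandularity = 0.109,
                                   radius_mm = 90, voxel_mm = 1,
                                   n_blobs = 1500,
                                   blob_sigma_mm = c(2, 5),
                                   z_spread = 0.25,
                                   skin_mm = 1.5) {
  if (missing(seed)) {
    abort("a seed is mandatory for reproducibility",
          class = "mammodose_seed")
  }
  if (target_glandularity < 0 || target_glandularity >= 1) {
    abort("target_glandularity must be in [0, 1)",
          class = "mammodose_phantom_geometry")
  }
  tmm <- thickness_cm * 10
  nx <- ceiling(2 * radius_mm / voxel_mm)
  ny <- ceiling(radius_mm / voxel_mm)
  nz <- ceiling(tmm / voxel_mm)
  x <- -radius_mm + (seq_len(nx) - 0.5) * voxel_mm
  y <- (seq_len(ny) - 0.5) * voxel_mm
  z <- (seq_len(nz) - 0.5) * voxel_mm
  r2 <- outer(x^2, y^2, `+`)
  inside <- r2 <= radius_mm^2

  labels <- array(0L, c(nx, ny, nz))
  # skin: within skin_mm of the curved surface, or top/bottom face
  rim <- inside & r2 > (radius_mm - skin_mm)^2
  z_face <- z < skin_mm | z > tmm - skin_mm
  for (k in seq_len(nz)) {
    sl <- ifelse(inside, 1L, 0L)
    sl[rim] <- 3L
    if (z_face[k]) sl[inside] <- 3L
    labels[, , k] <- sl
  }

  interior <- which(labels == 1L)
  rho <- c(adipose = material_adipose()$density,
           glandular = material_glandular()$density,
           skin = material_skin()$density)
  n_skin <- sum(labels == 3L)
  n_int <- length(interior)
  g <- target_glandularity
  n_g <- round(g * (n_int * rho[["adipose"]] + n_skin * rho[["skin"]]) /
                 (rho[["glandular"]] * (1 - g) + g * rho[["adipose"]]))
  if (n_g > n_int) {
    abort("target glandularity unreachable with this geometry",
          class = "mammodose_phantom_geometry")
  }

  if (n_g > 0) {
    idx <- arrayInd(interior, dim(labels))
    px <- x[idx[, 1]]; py <- y[idx[, 2]]; pz <- z[idx[, 3]]
    # proximity field: each voxel scores its distance to the nearest blob
    # center in units of that blob's size, so thresholding carves a union
    # of distinct roughly-ellipsoidal cores (fibroglandular strands)
    # rather than one merged central cloud
    field <- rep(-Inf, n_int)
    .with_seed(seed, {
      cx <- rnorm(n_blobs, 0, radius_mm / 2.5)
      cy <- rnorm(n_blobs, 0.45 * radius_mm, radius_mm / 3)
      cz <- rnorm(n_blobs, tmm / 2, tmm * z_spread)
      sig <- runif(n_blobs, blob_sigma_mm[1], blob_sigma_mm[2])
      for (b in seq_len(n_blobs)) {
        d2 <- (px - cx[b])^2 + (py - cy[b])^2 + (pz - cz[b])^2
        sc <- -d2 / sig[b]^2
        upd <- sc > field
        field[upd] <- sc[upd]
      }
    })
    ord <- order(field, decreasing = TRUE)
    labels[interior[ord[seq_len(n_g)]]] <- 2L
  }

  .new_phantom(labels, voxel_mm, c(-radius_mm, 0, 0),
               list(`0` = material_air(), `1` = material_adipose(),
                    `2` = material_glandular(), `3` = material_skin()),
               thickness_cm)
}

# per-label voxel counts, densities and glandular fractions (air excluded)
.tissue_label_stats <- function(phantom) {
  tabs <- table(phantom$labels)
  out <- NULL
  for (l in names(tabs)) {
    m <- phantom$label_map[[l]]
    if (m$density < 1e-2) next  # air
    out <- rbind(out, data.frame(
      label = as.integer(l), n = as.numeric(tabs[[l]]), rho = m$density,
      gfrac = m$glandular_fraction %||% 0))
  }
  out
}

#' Glandular mass fraction of a phantom
#'
#' Glandular mass over total tissue mass. Skin counts in the denominator
#' but never as glandular; homogeneous glandular/adipose mixture voxels
#' contribute their mixture fraction.
#'
#' @param phantom a `voxel_phantom`.
#' @return Fraction in `[0, 1]`.
#' @export
glandular_mass_fraction <- function(phantom) {
  st <- .tissue_label_stats(phantom)
  if (is.null(st)) {
    abort("phantom contains no tissue", class = "mammodose_phantom_labels")
  }
  sum(st$n * st$rho * st$gfrac) / sum(st$n * st$rho)
}

#' Replace the glandular/adipose interior by a homogeneous mixture
#'
#' All adipose and glandular voxels are relabelled to a single
#' glandular/adipose mixture whose mass fraction equals the phantom's
#' glandular-to-(glandular+adipose) mass ratio, so total tissue mass and
#' the overall glandular mass fraction are conserved. Skin and air are
#' untouched.
#'
#' @param phantom a `voxel_phantom`.
#' @return A `voxel_phantom` with the interior homogenized.
#' @export
homogenize <- function(phantom) {
  st <- .tissue_label_stats(phantom)
  # interior = every non-air, non-skin label
  skin_like <- vapply(as.character(st$label), function(l) {
    identical(phantom$label_map[[l]]$name, "skin")
  }, logical(1))
  int <- st[!skin_like, ]
  m_g <- sum(int$n * int$rho * int$gfrac)
  m_tot <- sum(int$n * int$rho)
  f <- m_g / m_tot
  mix <- mix_by_mass(list(material_glandular(), material_adipose()),
                     c(f, 1 - f),
                     name = sprintf("glandular/adipose %.1f%%", 100 * f))
  labels <- phantom$labels
  new_map <- list()
  mix_label <- 1L
  for (l in names(phantom$label_map)) {
    m <- phantom$label_map[[l]]
    if (m$density < 1e-2 || identical(m$name, "skin")) {
      new_map[[l]] <- m
    } else {
      labels[labels == as.integer(l)] <- mix_label
      new_map[[as.character(mix_label)]] <- mix
    }
  }
  .new_phantom(labels, phantom$voxel_mm, phantom$origin_mm, new_map,
               phantom$thickness_cm)
}

#' Default point-dosimeter layout
#'
#' Thirty positions (5 rows from chest wall to nipple, 6 columns across)
#' scaled to the phantom footprint so that every chip sits inside the
#' semicylinder with margin. Rows sit at fixed distances from the chest
#' wall; columns span 80% of the local half-width.
#'
#' @param radius_mm phantom footprint radius (mm).
#' @param rows_mm distances of the rows from the chest wall (mm).
#' @param n_cols chips per row.
#' @return Tibble with `position`, `x_mm`, `y_mm`.
#' @export
default_tld_layout <- function(radius_mm = 100,
                               rows_mm = c(15, 35, 55, 75, 95) *
                                 radius_mm / 100,
                               n_cols = 6) {
  rows <- purrr::map_dfr(seq_along(rows_mm), function(i) {
    y <- rows_mm[i]
    # local half-width with a 4 mm inset so whole chips stay inside
    w <- sqrt(pmax(radius_mm^2 - (y + 4)^2, 0)) - 4
    tibble(y_mm = y, x_mm = seq(-0.8 * w, 0.8 * w, length.out = n_cols))
  })
  tibble(position = seq_len(nrow(rows)), x_mm = rows$x_mm, y_mm = rows$y_mm)
}

#' Sensitive-volume (TLD chip) placement
#'
#' Places TLD-sized sensitive volumes (3.2 x 3.2 x 0.38 mm chips) at the
#' layout positions and the requested depth below the phantom entrance
#' surface. Errors if any chip would protrude from the phantom footprint
#' or thickness, naming the offending position.
#'
#' @param phantom a `voxel_phantom`.
#' @param depth_cm depth of the chip layer below the entrance (top)
#'   surface, in cm.
#' @param layout data frame with `x_mm`, `y_mm` (and optionally
#'   `position`) columns; defaults to the 30-position grid.
#' @param chip_mm chip dimensions (x, y, z) in mm.
#' @return Tibble with `position`, `x_mm`, `y_mm`, `z_mm` (chip center)
#'   and `dx_mm`, `dy_mm`, `dz_mm`.
#' @export
tld_positions <- function(phantom, depth_cm,
                          layout = NULL,
                          chip_mm = c(3.2, 3.2, 0.38)) {
  radius <- -phantom$origin_mm[1]
  if (is.null(layout)) layout <- default_tld_layout(radius)
  if (nrow(layout) == 0L) {
    return(tibble(position = integer(), x_mm = numeric(), y_mm = numeric(),
                  z_mm = numeric(), dx_mm = numeric(), dy_mm = numeric(),
                  dz_mm = numeric()))
  }
  if (!"position" %in% names(layout)) {
    layout$position <- seq_len(nrow(layout))
  }
  tmm <- phantom$thickness_cm * 10
  z_top <- tmm - depth_cm * 10
  z_c <- z_top - chip_mm[3] / 2
  if (z_c - chip_mm[3] / 2 < 0 || z_c + chip_mm[3] / 2 > tmm) {
    abort(sprintf("depth %.3g cm puts chips outside the phantom thickness",
                  depth_cm), class = "mammodose_phantom_geometry")
  }
  for (i in seq_len(nrow(layout))) {
    cx <- abs(layout$x_mm[i]) + chip_mm[1] / 2
    cy <- layout$y_mm[i] + chip_mm[2] / 2
    if (layout$y_mm[i] - chip_mm[2] / 2 < 0 || cx^2 + cy^2 > radius^2) {
      abort(sprintf("position %d (x=%.1f, y=%.1f) outside phantom footprint",
                    layout$position[i], layout$x_mm[i], layout$y_mm[i]),
            class = "mammodose_phantom_geometry")
    }
  }
  tibble(position = layout$position, x_mm = layout$x_mm,
         y_mm = layout$y_mm, z_mm = z_c,
         dx_mm = chip_mm[1], dy_mm = chip_mm[2], dz_mm = chip_mm[3])
}

## ---- serialization --------------------------------------------------------

.material_to_list <- function(m) {
  list(name = m$name, density = m$density,
       mass_fractions = as.list(m$mass_fractions),
       glandular_fraction = m$glandular_fraction %||% 0)
}

.material_from_list <- function(l) {
  structure(
    list(name = l$name, density = l$density,
         mass_fractions = unlist(l$mass_fractions),
         glandular_fraction = l$glandular_fraction %||% 0),
    class = "material"
  )
}

#' Phantom file round trip
#'
#' A phantom is stored as a little-endian uint8 raw label array plus a
#' JSON sidecar (`<path>.json`) holding shape, voxel size, origin,
#' thickness and the label -> material map. The round trip is lossless.
#'
#' @param phantom a `voxel_phantom`.
#' @param path path of the raw label file; the sidecar is `<path>.json`.
#' @export
write_phantom <- function(phantom, path) {
  labs <- as.integer(phantom$labels)
  if (any(labs < 0 | labs > 255)) {
    abort("labels must fit uint8", class = "mammodose_format")
  }
  writeBin(as.raw(labs), path)
  sidecar <- list(
    shape = dim(phantom$labels), voxel_mm = phantom$voxel_mm,
    origin_mm = phantom$origin_mm, thickness_cm = phantom$thickness_cm,
    label_map = lapply(phantom$label_map, .material_to_list)
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) {
    abort("missing JSON sidecar", class = "mammodose_format")
  }
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  shape <- as.integer(sc$shape)
  n <- prod(shape)
  raw <- readBin(path, "raw", n = n + 1L)
  if (length(raw) != n) {
    abort(sprintf("raw array has %d bytes, sidecar shape needs %d",
                  length(raw), n), class = "mammodose_format")
  }
  labels <- array(as.integer(raw), shape)
  label_map <- lapply(sc$label_map, .material_from_list)
  present <- as.character(sort(unique(as.vector(labels))))
  if (!all(present %in% names(label_map))) {
    abort("sidecar label_map does not cover all labels in the raw array",
          class = "mammodose_format")
  }
  .new_phantom(labels, sc$voxel_mm, sc$origin_mm, label_map,
               sc$thickness_cm)
}
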