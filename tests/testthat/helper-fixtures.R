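# Shared fixtures: tuned beam, coarse phantoms, and an independent
# layered-slab reference transport used as an oracle for the Woodcock
# engine.

# tuned 28 kV W/Rh beam (Rh thickness frozen from tune_filter to the
# 0.55 mm Al beam quality; tests that need the tuning itself redo it)
tuned_spectrum <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      s <- kramers_spectrum(28, inherent_be_mm = 0.8)
      fit <- tune_filter(s, material_rhodium(), target_hvl_mm = 0.55,
                         bracket = c(0.02, 0.08))
      s <- attenuate_spectrum(s, material_rhodium(), fit$thickness_mm)
      s$fluence <- s$fluence / sum(s$fluence)
      memo <<- s
    }
    memo
  }
})

coarse_homogeneous <- function(voxel_mm = 2) {
  build_homogeneous(radius_mm = 100, thickness_cm = 5, voxel_mm = voxel_mm)
}

# single-bin spectrum for monoenergetic scenarios
mono_spectrum <- function(energy_keV) {
  s <- kramers_spectrum(28, bin_keV = 0.25, inherent_be_mm = 0)
  s$energy_keV <- energy_keV
  s$fluence <- 1
  s$bin_keV <- 0
  s$kvp <- energy_keV
  s
}

# two-material slab phantom: upper half adipose, lower half glandular
two_layer_slab <- function(radius_mm = 80, thickness_cm = 4, voxel_mm = 2) {
  ph <- build_homogeneous(radius_mm, thickness_cm, voxel_mm,
                          material = material_adipose())
  nz <- dim(ph$labels)[3]
  lower <- seq_len(nz %/% 2)
  sl <- ph$labels[, , lower]
  sl[sl == 1L] <- 2L
  ph$labels[, , lower] <- sl
  ph$label_map[["2"]] <- material_glandular()
  ph
}

## ---- independent layered-slab reference transport -------------------------
## Explicit boundary-to-boundary voxel-walk photon MC on laterally infinite
## z-slabs: free paths sampled from the local material's attenuation
## coefficient with boundary re-sampling, Klein-Nishina (Kahn) incoherent
## scattering, Thomson coherent scattering, photoelectric absorption and a
## 1 keV cutoff. Completely separate code path from the Woodcock engine.

.ref_rotate <- function(ux, uy, uz, cth, phi) {
  st <- sqrt(pmax(0, 1 - cth^2))
  cp <- cos(phi); sp <- sin(phi)
  den2 <- 1 - uz^2
  safe <- den2 > 1e-12
  den <- sqrt(pmax(den2, 1e-12))
  nx <- ifelse(safe, ux * cth + st * (ux * uz * cp - uy * sp) / den,
               st * cp)
  ny <- ifelse(safe, uy * cth + st * (uy * uz * cp + ux * sp) / den,
               sign(uz) * st * sp)
  nz <- ifelse(safe, uz * cth - st * den * cp, sign(uz) * cth)
  nrm <- sqrt(nx^2 + ny^2 + nz^2)
  list(ux = nx / nrm, uy = ny / nrm, uz = nz / nrm)
}

.ref_kahn <- function(e_keV) {
  k <- e_keV / 510.99895
  n <- length(k)
  x <- numeric(n)
  todo <- rep(TRUE, n)
  while (any(todo)) {
    i <- which(todo)
    r1 <- runif(length(i)); r2 <- runif(length(i)); r3 <- runif(length(i))
    ki <- k[i]
    br1 <- r1 * (9 + 2 * ki) <= (1 + 2 * ki)
    xi <- ifelse(br1, 1 + 2 * ki * r2, (1 + 2 * ki) / (1 + 2 * ki * r2))
    ci <- 1 - (xi - 1) / ki
    acc <- ifelse(br1, r3 <= 4 * (1 / xi - 1 / xi^2),
                  r3 <= 0.5 * (ci^2 + 1 / xi))
    x[i[acc]] <- xi[acc]
    todo[i[acc]] <- FALSE
  }
  x
}

.ref_thomson <- function(n) {
  c <- numeric(n)
  todo <- rep(TRUE, n)
  while (any(todo)) {
    i <- which(todo)
    ci <- runif(length(i), -1, 1)
    acc <- runif(length(i)) <= 0.5 * (1 + ci^2)
    c[i[acc]] <- ci[acc]
    todo[i[acc]] <- FALSE
  }
  c
}

# layers: data frame with z_lo, z_hi (mm, descending stack) and a list
# column material; photons start at (x0, y0, z0) with direction dir.
# Returns per-history total deposit within r < r_max of the beam axis,
# binned in nz_bins equal z-bins of [z_tally_lo, z_tally_hi]:
# matrix [history_batch x bin] of deposits (batched for variance).
ref_slab_mc <- function(layers, start, dir, e0_keV, n, seed,
                        z_tally = c(0, 40), nz_bins = 8, r_max = 10,
                        cutoff = 1, n_batch = 20) {
  set.seed(seed)
  z_breaks <- sort(unique(c(layers$z_lo, layers$z_hi)))
  mat_of <- function(z) {
    idx <- rep(NA_integer_, length(z))
    for (i in seq_len(nrow(layers))) {
      sel <- z >= layers$z_lo[i] & z < layers$z_hi[i]
      idx[sel] <- i
    }
    idx
  }
  mu_lin <- function(li, e, kind) {
    out <- numeric(length(e))
    for (i in unique(li[!is.na(li)])) {
      m <- layers$material[[i]]
      sel <- !is.na(li) & li == i
      out[sel] <- mammodose:::.material_coef(m, e[sel], kind) *
        m$density / 10
    }
    out
  }
  bins <- seq(z_tally[1], z_tally[2], length.out = nz_bins + 1)
  batch_of <- function(h) ((h - 1) %% n_batch) + 1
  dep <- matrix(0, n_batch, nz_bins)

  x <- rep(start[1], n); y <- rep(start[2], n); z <- rep(start[3], n)
  ux <- rep(dir[1], n); uy <- rep(dir[2], n); uz <- rep(dir[3], n)
  e <- rep(e0_keV, n)
  hist_id <- seq_len(n)
  alive <- rep(TRUE, n)

  deposit <- function(xs, ys, zs, es, hs) {
    # lateral distance from the (possibly tilted) beam axis at this z
    t_ax <- (zs - start[3]) / dir[3]
    r <- sqrt((xs - (start[1] + dir[1] * t_ax))^2 +
                (ys - (start[2] + dir[2] * t_ax))^2)
    sel <- r < r_max & zs >= z_tally[1] & zs < z_tally[2]
    if (!any(sel)) return(invisible())
    b <- findInterval(zs[sel], bins, rightmost.closed = TRUE)
    bt <- batch_of(hs[sel])
    for (j in seq_along(b)) {
      dep[bt[j], b[j]] <<- dep[bt[j], b[j]] + es[j]
    }
  }

  zmin <- min(layers$z_lo); zmax <- max(layers$z_hi)
  for (step in 1:300) {
    if (!any(alive)) break
    i <- which(alive)
    li <- mat_of(z[i])
    esc <- is.na(li) | z[i] <= zmin | z[i] >= zmax
    if (any(esc)) {
      alive[i[esc]] <- FALSE
      i <- i[!esc]; li <- li[!esc]
      if (length(i) == 0L) next
    }
    mu_t <- mu_lin(li, e[i], "mu")
    s <- rexp(length(i)) / mu_t
    # distance to the layer boundary along z
    tb <- ifelse(uz[i] > 1e-12, (layers$z_hi[li] - z[i]) / uz[i],
                 ifelse(uz[i] < -1e-12, (layers$z_lo[li] - z[i]) / uz[i],
                        Inf))
    cross <- s >= tb
    adv <- ifelse(cross, tb + 1e-6, s)
    x[i] <- x[i] + ux[i] * adv
    y[i] <- y[i] + uy[i] * adv
    z[i] <- z[i] + uz[i] * adv
    ii <- i[!cross]
    if (length(ii) == 0L) next
    lii <- mat_of(z[ii])
    p_pe <- mu_lin(lii, e[ii], "pe") / mu_lin(lii, e[ii], "mu")
    p_coh <- mu_lin(lii, e[ii], "coh") / mu_lin(lii, e[ii], "mu")
    xi <- runif(length(ii))
    is_pe <- xi < p_pe
    is_coh <- !is_pe & xi < p_pe + p_coh
    is_inc <- !is_pe & !is_coh
    if (any(is_pe)) {
      j <- ii[is_pe]
      deposit(x[j], y[j], z[j], e[j], hist_id[j])
      alive[j] <- FALSE
    }
    if (any(is_coh)) {
      j <- ii[is_coh]
      rot <- .ref_rotate(ux[j], uy[j], uz[j], .ref_thomson(length(j)),
                         runif(length(j), 0, 2 * pi))
      ux[j] <- rot$ux; uy[j] <- rot$uy; uz[j] <- rot$uz
    }
    if (any(is_inc)) {
      j <- ii[is_inc]
      xr <- .ref_kahn(e[j])
      cth <- 1 - (xr - 1) / (e[j] / 510.99895)
      enew <- e[j] / xr
      deposit(x[j], y[j], z[j], e[j] - enew, hist_id[j])
      e[j] <- enew
      rot <- .ref_rotate(ux[j], uy[j], uz[j], cth,
                         runif(length(j), 0, 2 * pi))
      ux[j] <- rot$ux; uy[j] <- rot$uy; uz[j] <- rot$uz
      dead <- j[e[j] < cutoff]
      if (length(dead)) {
        deposit(x[dead], y[dead], z[dead], e[dead], hist_id[dead])
        alive[dead] <- FALSE
      }
    }
  }
  dep
}
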