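# Rendering of noiseless channels and microscope emulation.

# Quadratic affinity profile across a diffuse interface, anchored to the true
# partitioning: q(d) is the affinity -dG(d) (k_BT) at signed distance d (um)
# from the granule surface (negative inside). Inside the interface
# (|d| < w) it is the parabola through q(-w) = ln k_g, q(w) = 0 with interior
# maximum ln k_s; outside it takes the bulk values, so the rendered tubulin
# level cytosol * exp(q) realizes ln k_g and ln k_s exactly.
affinity_profile <- function(d, lnkg, lnks, w) {
  if (lnks <= max(0, lnkg))
    stop("surface affinity must exceed both bulk affinities")
  rho <- sqrt((lnks - lnkg) / lnks)
  d0 <- w * (rho - 1) / (rho + 1)
  alpha <- lnks / (w - d0)^2
  q <- lnks - alpha * (d - d0)^2
  q[d >= w] <- 0
  q[d <= -w] <- lnkg
  q
}

# draw one granule's true affinities; redraw until the interface profile is
# realizable (interior maximum above both bulk levels)
draw_affinities <- function(spec) {
  for (i in 1:200) {
    lnkg <- rnorm(1, spec$lnkg_mean, spec$lnkg_sd)
    lnks <- rnorm(1, spec$lnks_mean, spec$lnks_sd)
    if (lnks > max(0, lnkg) + 0.005) return(c(lnkg = lnkg, lnks = lnks))
  }
  stop("could not draw a realizable affinity pair")
}

# approximate signed Euclidean distance (um) to an ellipsoid surface with
# semi-axes (a, b, c) given coordinates already rotated into the granule frame
ellipsoid_sdf <- function(u, v, zz, a, b, c) {
  n <- sqrt((u / a)^2 + (v / b)^2 + (zz / c)^2)
  gn <- sqrt((u / a^2)^2 + (v / b^2)^2 + (zz / c^2)^2)
  d <- ifelse(n > 1e-6, (n - 1) * n / pmax(gn, 1e-12), -min(a, b, c))
  d
}

place_granules <- function(spec, geom) {
  n <- max(1L, rpois(1, spec$n_granules))
  g <- geom$coords
  base_z <- (spec$base_slice - 1) * spec$z_step
  top_z <- max(g$z)
  # radii first, largest placed first for reliable packing
  radii <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      r <- exp(rnorm(1, spec$radius_meanlog, spec$radius_sdlog))
      if (r >= spec$radius_range[1] && r <= spec$radius_range[2] &&
          top_z - r >= base_z + r) break
    }
    radii[i] <- r
  }
  radii <- sort(radii, decreasing = TRUE)
  half_seg <- spec$rect_length / 2
  placed <- list()
  for (i in seq_len(n)) {
    R <- radii[i]
    ok <- FALSE
    for (try in 1:500) {
      u <- runif(1, -(half_seg + spec$cap_radius), half_seg + spec$cap_radius)
      v <- runif(1, -spec$cap_radius, spec$cap_radius)
      if (stadium_sdf(u, v, half_seg, spec$cap_radius) > -(R + 0.15)) next
      # keep the granule clear of the nucleus
      en <- ((u - spec$nucleus_offset) / (spec$nucleus_semi[1] + R + 0.2))^2 +
        (v / (spec$nucleus_semi[2] + R + 0.2))^2
      if (en < 1) next
      zc <- runif(1, base_z + R, top_z - R)
      sep_ok <- TRUE
      for (p in placed) {
        need <- R + p$R + 1.0 # clear of dilation-fusion and of the neighbour's
        # interface ring, so partition windows stay uncontaminated
        if ((u - p$u)^2 + (v - p$v)^2 + (zc - p$z)^2 < need^2) {
          sep_ok <- FALSE; break
        }
      }
      if (!sep_ok) next
      ok <- TRUE
      break
    }
    if (!ok) {
      if (i == 1L) stop("granule placement failed after bounded retries")
      warning("granule placement saturated after ", i - 1L,
              " granules; remaining dropped")
      placed <- placed[seq_len(i - 1L)]
      break
    }
    aspect <- if (runif(1) < spec$frac_round) {
      min(1.5, 1 + abs(rnorm(1, 0, 0.18)))
    } else {
      runif(1, 1.5, spec$aspect_max)
    }
    aff <- draw_affinities(spec)
    placed[[i]] <- list(u = u, v = v, z = zc, R = R, aspect = aspect,
                        phi = runif(1, 0, 180),
                        lnkg = aff[["lnkg"]], lnks = aff[["lnks"]])
  }
  placed
}

#' Render the noiseless granule and tubulin channels of a synthetic cell
#'
#' The granule channel is the cytosol level inside the cell plus, per granule,
#' a radially smoothed (tanh) step of half-width `interface_width`. In
#' depolymerized mode the tubulin channel is the cytosol level times
#' `exp(q(d))`, with `q(d)` the quadratic affinity landscape mapped onto the
#' signed distance to the granule surface, so the true `ln k_g` and `ln k_s`
#' are realized exactly. In filament mode, straight segments are laid down
#' with placement density following the same Boltzmann weight.
#'
#' @param geom geometry from [generate_cell_geometry()].
#' @param spec a [scene_spec()].
#' @param granules optional pre-placed granule list (default: sampled).
#' @return list with noiseless arrays `granule`, `tubulin`, `nucleus` and the
#'   ground-truth tibble `truth` (one row per rendered granule).
#' @export
render_channels <- function(geom, spec, granules = NULL) {
  ny <- spec$grid_dim[1]; nx <- spec$grid_dim[2]; nz <- spec$grid_dim[3]
  g <- geom$coords
  if (is.null(granules)) granules <- place_granules(spec, geom)
  base_z <- (spec$base_slice - 1) * spec$z_step
  zc_mid <- base_z + 3 * spec$z_step
  zprof <- 1 + spec$z_bump_amp * exp(-0.5 * ((g$z - zc_mid) / spec$z_bump_sd)^2)

  cyt <- spec$cytosol_level
  gran_ch <- array(0, c(ny, nx, nz))
  tub_ch <- array(0, c(ny, nx, nz))
  nuc_ch <- array(0, c(ny, nx, nz))
  for (iz in seq_len(nz)) {
    inz <- geom$in_cell[, , iz]
    gran_ch[, , iz] <- cyt * inz
    tub_ch[, , iz] <- if (spec$tubulin_mode == "depolymerized") cyt * inz
                      else 0.3 * cyt * inz
    nuc_ch[, , iz] <- 0.1 * inz + 5 * geom$nucleus3d[, , iz]
  }

  th_cell <- geom$orientation * pi / 180
  for (gr in granules) {
    # granule centre in image coordinates
    xc <- cos(th_cell) * gr$u - sin(th_cell) * gr$v + geom$centre[1]
    yc <- sin(th_cell) * gr$u + cos(th_cell) * gr$v + geom$centre[2]
    a <- gr$R * sqrt(gr$aspect); b <- gr$R / sqrt(gr$aspect); cz <- b
    ext <- a + max(spec$landscape_width, 4 * spec$interface_width) + 0.15
    ix <- which(abs(g$x - xc) <= ext)
    iy <- which(abs(g$y - yc) <= ext)
    iz <- which(abs(g$z - gr$z) <= ext)
    if (!length(ix) || !length(iy) || !length(iz)) next
    phi <- (gr$phi + geom$orientation) * pi / 180
    dx <- rep(g$x[ix] - xc, each = length(iy))
    dy <- rep(g$y[iy] - yc, length(ix))
    uu <- cos(phi) * dx + sin(phi) * dy
    vv <- -sin(phi) * dx + cos(phi) * dy
    for (k in seq_along(iz)) {
      zz <- g$z[iz[k]] - gr$z
      d <- ellipsoid_sdf(uu, vv, zz, a, b, cz)
      # granule marker: tanh step from cytosol to interior level
      fac <- 1 + (spec$interior_ratio - 1) *
        0.5 * (1 - tanh(d / spec$interface_width))
      gblk <- matrix(fac, length(iy), length(ix))
      gran_ch[iy, ix, iz[k]] <- gran_ch[iy, ix, iz[k]] * gblk
      if (spec$tubulin_mode == "depolymerized") {
        q <- affinity_profile(d, gr$lnkg, gr$lnks, spec$landscape_width)
        tub_ch[iy, ix, iz[k]] <- tub_ch[iy, ix, iz[k]] *
          matrix(exp(q), length(iy), length(ix))
      }
    }
  }
  if (spec$tubulin_mode == "filament") {
    tub_ch <- tub_ch + render_filaments(geom, spec, granules)
  }
  for (iz in seq_len(nz)) {
    gran_ch[, , iz] <- gran_ch[, , iz] * zprof[iz]
    tub_ch[, , iz] <- tub_ch[, , iz] * zprof[iz]
  }
  th <- geom$orientation
  truth <- tibble::tibble(
    granule = seq_along(granules),
    x_um = vapply(granules, function(p)
      cos(th_cell) * p$u - sin(th_cell) * p$v + geom$centre[1], 0),
    y_um = vapply(granules, function(p)
      sin(th_cell) * p$u + cos(th_cell) * p$v + geom$centre[2], 0),
    z_um = vapply(granules, function(p) p$z, 0),
    radius_um = vapply(granules, function(p) p$R, 0),
    aspect = vapply(granules, function(p) p$aspect, 0),
    phi_deg = vapply(granules, function(p) (p$phi + th) %% 180, 0),
    lnkg_true = vapply(granules, function(p) p$lnkg, 0),
    lnks_true = vapply(granules, function(p) p$lnks, 0),
    interface_width = spec$interface_width,
    landscape_width = spec$landscape_width,
    orientation_deg = th,
    base_slice = spec$base_slice
  )
  list(granule = gran_ch, tubulin = tub_ch, nucleus = nuc_ch, truth = truth)
}

# straight filament segments; midpoint density follows the Boltzmann weight of
# the granule surface landscape, amplified by the filament/sub-unit contact
# ratio. Curvature is not simulated (microtubules are rigid at granule scale).
render_filaments <- function(geom, spec, granules, affinity_scale = 20) {
  ny <- spec$grid_dim[1]; nx <- spec$grid_dim[2]; nz <- spec$grid_dim[3]
  g <- geom$coords
  out <- array(0, c(ny, nx, nz))
  base_z <- (spec$base_slice - 1) * spec$z_step
  top_z <- max(g$z)
  n_seg <- spec$filament_density
  th_cell <- geom$orientation * pi / 180
  centres <- lapply(granules, function(p) {
    c(cos(th_cell) * p$u - sin(th_cell) * p$v + geom$centre[1],
      sin(th_cell) * p$u + cos(th_cell) * p$v + geom$centre[2], p$z)
  })
  wmax <- exp(affinity_scale * max(c(0.0, vapply(granules, function(p) p$lnks, 0))))
  placed <- 0
  guard <- 0
  while (placed < n_seg && guard < n_seg * 500) {
    guard <- guard + 1
    u <- runif(1, -(spec$rect_length / 2 + spec$cap_radius),
               spec$rect_length / 2 + spec$cap_radius)
    v <- runif(1, -spec$cap_radius, spec$cap_radius)
    if (stadium_sdf(u, v, spec$rect_length / 2, spec$cap_radius) > -0.2) next
    xm <- cos(th_cell) * u - sin(th_cell) * v + geom$centre[1]
    ym <- sin(th_cell) * u + cos(th_cell) * v + geom$centre[2]
    zm <- runif(1, base_z + 0.1, top_z - 0.1)
    q <- 0
    for (i in seq_along(granules)) {
      p <- granules[[i]]; cc <- centres[[i]]
      d <- sqrt((xm - cc[1])^2 + (ym - cc[2])^2 + (zm - cc[3])^2) - p$R
      q <- max(q, affinity_profile(d, p$lnkg, p$lnks, spec$landscape_width))
    }
    if (runif(1) > exp(affinity_scale * q) / wmax) next
    placed <- placed + 1
    ang <- runif(1, 0, pi)
    half <- spec$filament_length / 2
    ts <- seq(-half, half, by = spec$pitch_xy / 2)
    xs <- xm + cos(ang) * ts; ys <- ym + sin(ang) * ts
    jx <- round((xs / spec$pitch_xy) + (nx + 1) / 2)
    jy <- round((ys / spec$pitch_xy) + (ny + 1) / 2)
    jz <- round(zm / spec$z_step) + 1
    keep <- jx >= 1 & jx <= nx & jy >= 1 & jy <= ny & jz >= 1 & jz <= nz
    for (k in which(keep)) {
      if (geom$in_cell[jy[k], jx[k], jz]) {
        out[jy[k], jx[k], jz] <- out[jy[k], jx[k], jz] + spec$cytosol_level
      }
    }
  }
  out
}

#' Apply optics (PSF blur) and shot noise to rendered channels
#'
#' A separable Gaussian blur (`psf_sigma_xy`, `psf_sigma_z`) emulates the
#' confocal point spread function; blur alone conserves total intensity.
#' Shot noise is scaled-Poisson: a voxel of mean `I` becomes
#' `Poisson(photon_scale * I) / photon_scale`, so variance/mean = 1/photon_scale.
#'
#' @param channels list of noiseless arrays (from [render_channels()]).
#' @param spec a [scene_spec()].
#' @return named list of [channel_stack()] objects.
#' @export
apply_optics_and_noise <- function(channels, spec) {
  if (spec$psf_sigma_xy < 0 || spec$psf_sigma_z < 0) stop("negative PSF sigma")
  sx <- spec$psf_sigma_xy / spec$pitch_xy
  sz <- spec$psf_sigma_z / spec$z_step
  out <- list()
  for (nm in setdiff(names(channels), "truth")) {
    v <- channels[[nm]]
    v <- cpp_gauss3d(v, dim(v), sx, sx, sz, FALSE)
    if (spec$photon_scale > 0) {
      v[] <- rpois(length(v), pmax(v, 0) * spec$photon_scale) /
        spec$photon_scale
    }
    out[[nm]] <- channel_stack(v, pitch_xy = spec$pitch_xy,
                               z_step = spec$z_step, channel = nm)
  }
  out
}

#' Generate a seeded ensemble of synthetic acquisitions
#'
#' Renders `n_cells` cells with per-cell orientation and centre jitter and
#' per-cell granule populations. Identical `spec` and `seed` give identical
#' output.
#'
#' @param spec a [scene_spec()].
#' @param n_cells number of cells (>= 1).
#' @param seed integer seed; defaults to `spec$seed`.
#' @return list with `cells` (each: named list of [channel_stack()]s plus
#'   `truth` and `orientation`) and the pooled ground-truth tibble `truth`.
#' @export
generate_ensemble <- function(spec, n_cells, seed = spec$seed) {
  stopifnot(n_cells >= 1)
  set.seed(seed)
  cells <- vector("list", n_cells)
  truths <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    repeat {
      ori <- rnorm(1, 0, spec$orientation_sd)
      if (abs(ori) <= spec$orientation_max) break
    }
    ctr <- runif(2, -spec$centre_jitter, spec$centre_jitter)
    geom <- generate_cell_geometry(spec, orientation = ori, centre = ctr)
    ch <- render_channels(geom, spec)
    stacks <- apply_optics_and_noise(ch, spec)
    tr <- dplyr::mutate(ch$truth, cell = i, .before = 1)
    cells[[i]] <- list(stacks = stacks, truth = tr, orientation = ori,
                       centre = ctr)
    truths[[i]] <- tr
  }
  list(cells = cells, truth = dplyr::bind_rows(truths), spec = spec,
       seed = seed)
}
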