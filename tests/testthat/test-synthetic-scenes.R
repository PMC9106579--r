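test_that("cell geometry matches the prescribed stadium pattern", {
  spec <- small_spec()
  geom <- generate_cell_geometry(spec)
  area <- sum(geom$cell2d) * spec$pitch_xy^2
  nominal <- scene_footprint_area(spec, nominal = TRUE)
  expect_gt(area, 0.85 * nominal)
  expect_lt(area, 1.10 * nominal)
  # zero orientation jitter: long axis exactly horizontal
  m <- granuleface:::mask_moments(geom$cell2d)
  expect_lt(abs(m$theta), 0.5)
  # nucleus centroid offset into the left hemisphere
  nm <- granuleface:::mask_moments(geom$nucleus2d)
  expect_lt(nm$cx, m$cx)
})

test_that("a nucleus that cannot fit in the footprint is rejected", {
  expect_error(small_spec(nucleus_offset = -25), "footprint")
})

test_that("rendered tubulin realizes the prescribed partitioning exactly", {
  spec <- small_spec(photon_scale = 0)
  geom <- generate_cell_geometry(spec)
  gr <- list(list(u = 1.5, v = 0.8, z = 1.2, R = 0.8, aspect = 1, phi = 0,
                  lnkg = -0.05, lnks = 0.1))
  ch <- render_channels(geom, spec, granules = gr)
  g <- granuleface:::grid_coords(spec)
  iz <- which.min(abs(g$z - 1.2))
  iy <- which.min(abs(g$y - 0.8))
  ix <- which.min(abs(g$x - 1.5))
  zf <- 1 + spec$z_bump_amp *
    exp(-0.5 * ((g$z[iz] - (0.4 + 0.6)) / spec$z_bump_sd)^2)
  centre <- ch$tubulin[iy, ix, iz] / zf
  cytosol <- ch$tubulin[iy, 5 + which.min(abs(g$x + 3)), iz] / zf
  # noiseless level at the granule centre / cytosol equals k_g exactly
  expect_equal(centre / cytosol, exp(-0.05), tolerance = 1e-9)
  # maximum of the noiseless profile equals cytosol * k_s at |d| < w
  row <- ch$tubulin[iy, , iz] / zf
  expect_equal(max(row), cytosol * exp(0.1), tolerance = 5e-4)
  dmax <- abs(abs(g$x[which.max(row)] - 1.5) - 0.8)
  expect_lt(dmax, spec$landscape_width)
})

test_that("zero-affinity granules leave the tubulin channel uniform", {
  spec <- small_spec(photon_scale = 0)
  geom <- generate_cell_geometry(spec)
  gr <- list(list(u = 1.5, v = 0.8, z = 1.2, R = 0.7, aspect = 1, phi = 0,
                  lnkg = 1e-12, lnks = 2e-12))
  ch <- render_channels(geom, spec, granules = gr)
  vals <- ch$tubulin[, , 7][geom$in_cell[, , 7]]
  expect_lt(diff(range(vals)) / mean(vals), 1e-9)
})

test_that("granule marker interior reaches the prescribed contrast", {
  spec <- small_spec(photon_scale = 0, interior_ratio = 10)
  geom <- generate_cell_geometry(spec)
  gr <- list(list(u = 1.5, v = 0.8, z = 1.2, R = 0.8, aspect = 1, phi = 0,
                  lnkg = -0.016, lnks = 0.066))
  ch <- render_channels(geom, spec, granules = gr)
  g <- granuleface:::grid_coords(spec)
  iz <- which.min(abs(g$z - 1.2)); iy <- which.min(abs(g$y - 0.8))
  ix <- which.min(abs(g$x - 1.5))
  # cytosol level in the same plane, far from the granule
  iy0 <- which.min(abs(g$y - 0)); ix0 <- which.min(abs(g$x + 2))
  cyt <- ch$granule[iy0, ix0, iz]
  expect_gt(cyt, 0)
  expect_gte(ch$granule[iy, ix, iz], 9.9 * cyt)
})

test_that("optics conserve intensity and shot noise is scaled-Poisson", {
  spec <- small_spec(photon_scale = 0)
  bad <- spec
  bad$psf_sigma_xy <- -1
  expect_error(apply_optics_and_noise(list(a = array(1, c(8, 8, 4))), bad),
               "negative")
  # blur conserves the total of an interior-supported signal
  arr <- array(0, c(64, 64, 12))
  arr[30:34, 30:34, 5:8] <- 7
  st <- apply_optics_and_noise(list(x = arr), spec)
  expect_equal(sum(st$x$values), sum(arr), tolerance = 1e-6)
  # single unit voxel becomes a Gaussian blob of the stated sigma
  arr2 <- array(0, c(33, 33, 7))
  arr2[17, 17, 4] <- 1
  st2 <- apply_optics_and_noise(list(x = arr2), spec)
  sl <- st2$x$values[, , 4]
  sx <- spec$psf_sigma_xy / spec$pitch_xy
  expect_equal(sl[17, 18] / sl[17, 17], exp(-0.5 / sx^2), tolerance = 1e-3)
  # flat field: variance/mean is 1/photon_scale
  spec2 <- small_spec(photon_scale = 200, psf_sigma_xy = 0, psf_sigma_z = 0)
  set.seed(4)
  flat <- array(3, c(100, 100, 10))
  stn <- apply_optics_and_noise(list(x = flat), spec2)
  vm <- var(as.vector(stn$x$values)) / mean(stn$x$values)
  expect_equal(vm, 1 / 200, tolerance = 0.1)
})

test_that("ensembles are deterministic under a fixed seed", {
  spec <- small_spec(photon_scale = 300)
  e1 <- generate_ensemble(spec, 2, seed = 5)
  e2 <- generate_ensemble(spec, 2, seed = 5)
  expect_identical(e1$truth, e2$truth)
  expect_identical(e1$cells[[1]]$stacks$granule$values,
                   e2$cells[[1]]$stacks$granule$values)
  # truth table row count equals total rendered granules
  expect_equal(nrow(e1$truth),
               sum(vapply(e1$cells, function(cl) nrow(cl$truth), 0)))
})

test_that("interface position sampler matches the Boltzmann oracle", {
  m <- adsorption_model(R = 4, w = 40, gamma_tg = 18, gamma_tc = 15,
                        gamma_cg = 16, temperature = 300)
  set.seed(11)
  xs <- sample_interface_positions(m, 2e4)
  # empirical mean energy matches quadrature within Monte-Carlo error
  e_emp <- mean(suppressWarnings(finite_interface_energy(m, xs)))
  e_th <- mean_interface_energy(m)
  se <- sd(suppressWarnings(finite_interface_energy(m, xs))) / sqrt(length(xs))
  expect_lt(abs(e_emp - e_th), 3 * se + 1e-4)
  # histogram mode sits at the numeric minimizer of the energy landscape
  opt <- optimize(function(x) finite_interface_energy(m, x),
                  c(-m$w + 1e-6, m$w - 1e-6))
  h <- hist(xs, breaks = seq(-m$w, m$w, length.out = 41), plot = FALSE)
  expect_lt(abs(h$mids[which.max(h$counts)] - opt$minimum),
            2 * diff(h$mids[1:2]))
  # symmetric landscape: sample mean of x is 0 within 3 standard errors
  m0 <- adsorption_model(R = 4, w = 40, gamma_tg = 15, gamma_tc = 15,
                         gamma_cg = 16, temperature = 300)
  set.seed(12)
  x0 <- sample_interface_positions(m0, 2e4)
  expect_lt(abs(mean(x0)), 3 * sd(x0) / sqrt(length(x0)))
  # vanishing interfacial energy: flat distribution (KS test not rejected)
  mf <- adsorption_model(R = 4, w = 40, gamma_tg = 15, gamma_tc = 15,
                         gamma_cg = 1e-9, temperature = 300)
  set.seed(13)
  xf <- sample_interface_positions(mf, 5000)
  ks <- suppressWarnings(ks.test((xf + 40) / 80, "punif"))
  expect_gt(ks$p.value, 0.01)
})
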