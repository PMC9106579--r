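test_that("reference normalization is a masked point-wise ratio", {
  crop <- matrix(2, 11, 11)
  ref <- matrix(2, 11, 11)
  expect_equal(normalize_granule_image(crop, ref), matrix(1, 11, 11))
  # 1.2x the reference reads as a 20% enhancement
  expect_equal(normalize_granule_image(1.2 * ref, ref)[1, 1], 1.2)
  crop[3, 3] <- NA
  out <- normalize_granule_image(crop, ref)
  expect_true(is.na(out[3, 3]))
  ref0 <- ref; ref0[5, 5] <- 0
  expect_warning(out0 <- normalize_granule_image(crop, ref0), "zero")
  expect_true(is.na(out0[5, 5]))
})

test_that("granules are binned by radius and shape as prescribed", {
  g <- tibble::tibble(R_px = c(4, 3, 5.9, 6, 9.5),
                      R_um = c(4, 3, 5.9, 6, 9.5) * 0.065,
                      ellipticity = c(1.2, 1.4, 1.51, 5.2, 1.0))
  out <- bin_granules(g)
  # first size bin [3, 6) px is labelled 0.26 um
  expect_equal(out$radius_bin[1:3], rep(4 * 0.065, 3))
  expect_equal(out$radius_bin[4], 7 * 0.065)
  expect_equal(out$shape_class, c("round", "round", "elongated", "elongated",
                                  "round"))
  expect_true(out$e_bin[4] > out$e_bin[3]) # sub-binned by axis ratio
})

test_that("maps average contributors with counts and support rotation", {
  crops <- list(matrix(1, 21, 21), matrix(1, 21, 21))
  mp <- make_maps(crops, mode = "distribution")
  expect_true(all(mp$values == 1))
  expect_true(all(mp$count == 2))
  # a single granule's map equals its own crop
  c1 <- matrix(runif(441), 21, 21)
  mp1 <- make_maps(list(c1), mode = "averaged")
  expect_equal(mp1$values, c1)
  # rotation closure at 90 degrees (exact on the grid)
  rot90 <- function(m) t(m[rev(seq_len(nrow(m))), ])
  set.seed(2)
  crops2 <- list(matrix(runif(441), 21, 21), matrix(runif(441), 21, 21))
  m_a <- make_maps(lapply(crops2, rot90))
  m_b <- make_maps(crops2)
  expect_equal(m_a$values, rot90(m_b$values), tolerance = 1e-12)
})

test_that("g(r) equals the brute-force average over contributing pixels", {
  set.seed(3)
  crops <- lapply(1:3, function(i) {
    m <- matrix(runif(41 * 41), 41, 41)
    if (i == 2) m[1:5, ] <- NA
    m
  })
  prof <- radial_profile(crops, r_max_px = 15)
  # independent oracle: loop over every pixel of every crop
  ctr <- c(21, 21)
  acc <- vector("list", 16)
  for (m in crops) for (y in 1:41) for (x in 1:41) {
    r <- round(sqrt((y - ctr[1])^2 + (x - ctr[2])^2))
    if (r <= 15 && !is.na(m[y, x]))
      acc[[r + 1]] <- c(acc[[r + 1]], m[y, x])
  }
  for (r in 0:15) {
    expect_equal(prof$g[r + 1], mean(acc[[r + 1]]), tolerance = 1e-12)
    expect_equal(prof$n[r + 1], length(acc[[r + 1]]))
    if (length(acc[[r + 1]]) > 1)
      expect_equal(prof$se[r + 1],
                   sd(acc[[r + 1]]) / sqrt(length(acc[[r + 1]])),
                   tolerance = 1e-12)
  }
  # uniform crops give g(r) = 1 everywhere
  flat <- radial_profile(list(matrix(1, 41, 41)), r_max_px = 15)
  expect_true(all(abs(flat$g - 1) < 1e-12))
})

test_that("azimuthal averaging of a uniform-count map matches g(r)", {
  set.seed(4)
  crops <- lapply(1:4, function(i) matrix(runif(41 * 41), 41, 41))
  prof <- radial_profile(crops, r_max_px = 12)
  mp <- make_maps(crops, mode = "distribution")
  rmap <- round(granuleface:::crop_radius_px(c(41, 41)))
  for (r in 0:12) {
    expect_equal(mean(mp$values[rmap == r]), prof$g[r + 1], tolerance = 1e-6)
  }
  # a ring fixture peaks at its radius
  ring <- matrix(1, 41, 41)
  rr <- granuleface:::crop_radius_px(c(41, 41))
  ring[abs(rr - 8) < 0.5] <- 2
  pr <- radial_profile(list(ring), r_max_px = 15)
  expect_equal(pr$r_um[which.max(pr$g)], 8 * 0.065)
})

test_that("signed surface distances follow the outline geometry", {
  # a filled circle of radius 10 px centred in a 41x41 crop
  rr <- granuleface:::crop_radius_px(c(41, 41))
  cs_mask <- rr <= 10
  cs <- which(cs_mask, arr.ind = TRUE)
  ol <- granuleface:::outline_pixels(cs_mask)
  g <- tibble::tibble(granule = 1, cross_section = list(cs),
                      outline = list(ol))
  crop <- matrix(1, 41, 41)
  prof <- surface_profile(g[1, ], crop, origin = c(y = 1L, x = 1L, z = 1L),
                          d_max_px = 15)
  # uniform crop: g_s(d) = 1 at every distance
  expect_true(all(abs(prof$g_s - 1) < 1e-12))
  # outline pixels are at d = 0, the centre pixel near -10 px
  expect_true(0 %in% round(prof$d_um / 0.065))
  expect_lte(min(round(prof$d_um / 0.065)), -9)
  d_centre <- -min(prof$d_um[prof$n > 0]) / 0.065
  expect_equal(d_centre, 10, tolerance = 0.15)
})

test_that("negative control maps fluctuate around one", {
  spec <- small_spec(photon_scale = 500)
  cfg <- pipeline_config(spec = spec, n_cells = 6, seed = 31, min_batch = 3,
                         canvas = spec$grid_dim[1:2], min_quality = 0.3)
  out <- suppressWarnings(run_pipeline(
    cfg, stages = c("simulate", "prep", "detect", "reference", "correlate"),
    verbose = FALSE))
  g <- out$correlate$granules[out$correlate$granules$kept, ]
  expect_gte(nrow(g), 3)
  set.seed(77)
  nc <- negative_control(g, out$prep$records, out$correlate$references)
  v <- nc$tubulin$values[nc$tubulin$count > 0]
  se <- sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))
  expect_lt(abs(mean(v, na.rm = TRUE) - 1), max(3 * se, 0.02))
  # determinism of the cell assignment under a fixed seed
  set.seed(77)
  nc2 <- negative_control(g, out$prep$records, out$correlate$references)
  expect_equal(nc$tubulin$values, nc2$tubulin$values)
  expect_error(negative_control(g, out$prep$records[1],
                                out$correlate$references),
               "two cells")
})

test_that("voxel-wise cross-correlation behaves at its limits", {
  set.seed(6)
  a <- array(rnorm(40 * 40 * 8, 10, 1), c(40, 40, 8))
  rec_same <- list(norm = list(granule = channel_stack(a),
                               tubulin = channel_stack(a)))
  out <- voxel_cross_correlation(list(rec_same))
  expect_equal(out$rho[1], 1)
  b <- array(rnorm(50 * 50 * 40, 10, 1), c(50, 50, 40))
  cc <- array(rnorm(50 * 50 * 40, 10, 1), c(50, 50, 40))
  rec_ind <- list(norm = list(granule = channel_stack(b),
                              tubulin = channel_stack(cc)))
  out2 <- voxel_cross_correlation(list(rec_ind))
  expect_lt(abs(out2$rho[1]), 0.05)
  # too few valid voxels: cell skipped
  small <- list(norm = list(granule = channel_stack(array(1, c(3, 3, 2))),
                            tubulin = channel_stack(array(1, c(3, 3, 2)))))
  expect_equal(nrow(voxel_cross_correlation(list(small))), 0)
})
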