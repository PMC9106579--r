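test_that("threshold sweep finds a stable plateau at the true blob count", {
  st <- sphere_stack(list(c(16, 16, 6), c(44, 20, 6), c(30, 46, 6)),
                     radii = c(5, 5, 5))
  sw <- preprocess_and_sweep(st, min_quality = 0.4)
  expect_null(sw$discard)
  counts <- sw$sweep$n_blobs
  # a plateau with exactly 3 blobs spanning at least 20 levels,
  # and the chosen level inside it
  expect_gte(sum(counts == 3), 20)
  expect_equal(sw$sweep$n_blobs[sw$chosen_level], 3)
  gt <- extract_granules(st, sw, matrix(TRUE, 64, 64), matrix(FALSE, 64, 64))
  expect_equal(sum(gt$kept), 3)
  # single sphere: exactly one blob at the chosen threshold
  st1 <- sphere_stack(list(c(32, 32, 6)), radii = 6)
  sw1 <- preprocess_and_sweep(st1, min_quality = 0.4)
  expect_equal(sw1$sweep$n_blobs[sw1$chosen_level], 1)
})

test_that("pure noise fails the minimum quality factor", {
  set.seed(17)
  arr <- array(rnorm(64 * 64 * 8, 1, 0.1), c(64, 64, 8))
  st <- channel_stack(arr)
  sw <- preprocess_and_sweep(st)
  expect_false(is.null(sw$discard))
})

test_that("granule geometry and discard rules follow the detection contract", {
  # solid sphere radius 6 px: kept, R_SG = 6 px, negligible centroid shift
  st <- sphere_stack(list(c(32, 32, 6)), radii = 6, noise_sd = 0)
  sw <- preprocess_and_sweep(st, min_quality = 0.3)
  gt <- extract_granules(st, sw, matrix(TRUE, 64, 64), matrix(FALSE, 64, 64))
  expect_true(gt$kept[1])
  expect_equal(gt$R_px[1], 6, tolerance = 0.12)
  expect_lt(gt$centroid_shift[1], 0.5)
  # sphere radius 2 px: below the 3-px diffraction floor (threshold at the
  # blob's half height so the detected set is the rendered sphere itself)
  st2 <- sphere_stack(list(c(32, 32, 6)), radii = 2, noise_sd = 0)
  sw2 <- list(filtered = stack_values(st2), threshold = 5)
  gt2 <- extract_granules(st2, sw2, matrix(TRUE, 64, 64),
                          matrix(FALSE, 64, 64))
  expect_false(gt2$kept[1])
  expect_equal(gt2$reason[1], "below diffraction floor")
  # two spheres 4 px apart surface-to-surface fuse on 3-px dilation
  st3 <- sphere_stack(list(c(32, 24, 6), c(32, 38, 6)), radii = c(5, 5),
                      noise_sd = 0)
  sw3 <- preprocess_and_sweep(st3, min_quality = 0)
  gt3 <- extract_granules(st3, sw3, matrix(TRUE, 64, 64),
                          matrix(FALSE, 64, 64))
  expect_true(all(gt3$reason[!gt3$kept] == "fused on dilation"))
  expect_equal(sum(gt3$kept), 0)
})

test_that("detection is equivariant under intensity rescaling", {
  st <- sphere_stack(list(c(20, 20, 6), c(44, 40, 6)), radii = c(5, 6))
  sw <- preprocess_and_sweep(st)
  st2 <- st
  st2$values <- st2$values * 3
  sw2 <- preprocess_and_sweep(st2)
  expect_equal(sw2$threshold, 3 * sw$threshold, tolerance = 1e-8)
  gt <- extract_granules(st, sw, matrix(TRUE, 64, 64), matrix(FALSE, 64, 64))
  gt2 <- extract_granules(st2, sw2, matrix(TRUE, 64, 64),
                          matrix(FALSE, 64, 64))
  expect_equal(gt$R_px, gt2$R_px)
  expect_equal(gt$y, gt2$y)
})

test_that("ellipticity is invariant under 90-degree rotation", {
  spec <- small_spec(photon_scale = 0)
  cell <- one_cell(spec, granules = list(
    list(u = 1.0, v = 0.5, z = 1.2, R = 0.7, aspect = 1.8, phi = 30,
         lnkg = -0.016, lnks = 0.066)))
  rec <- prep_one(cell)
  sw <- preprocess_and_sweep(rec$norm$granule)
  gt <- extract_granules(rec$norm$granule, sw, rec$cell2d, rec$nucleus2d)
  st <- rec$norm$granule
  rot <- function(a) aperm(a[, rev(seq_len(dim(a)[2])), , drop = FALSE],
                           c(2, 1, 3))
  st_r <- channel_stack(rot(st$values), valid = rot(st$valid))
  sw_r <- preprocess_and_sweep(st_r)
  gt_r <- extract_granules(st_r, sw_r, t(rec$cell2d[, rev(seq_len(160))]),
                           t(rec$nucleus2d[, rev(seq_len(160))]))
  i <- which.max(gt$R_px); j <- which.max(gt_r$R_px)
  expect_equal(gt$ellipticity[i], gt_r$ellipticity[j], tolerance = 1e-6)
})

test_that("crops are centred and masked correctly", {
  spec <- small_spec(photon_scale = 0)
  cell <- one_cell(spec, granules = list(
    list(u = 0.5, v = 0.3, z = 1.2, R = 0.75, aspect = 1, phi = 0,
         lnkg = -0.016, lnks = 0.066)))
  rec <- prep_one(cell)
  sw <- preprocess_and_sweep(rec$norm$granule)
  gt <- extract_granules(rec$norm$granule, sw, rec$cell2d, rec$nucleus2d)
  g <- gt[which.max(gt$R_px), ]
  cr <- crop_granule_images(rec, g, size = 221L)
  # crop centre pixel corresponds to the granule centroid pixel
  expect_equal(cr$granule[111, 111],
               stack_values(rec$norm$granule)[round(g$y), round(g$x),
                                              g$z_plane])
  # out-of-field margin is masked
  expect_true(anyNA(cr$granule))
})

test_that("brightness filter enforces contrast and outlier rules", {
  mk_row <- function(level, env_level = 1) {
    crop <- matrix(env_level, 41, 41)
    shape <- matrix(FALSE, 41, 41)
    shape[17:25, 17:25] <- TRUE
    crop[shape] <- level
    tibble::tibble(granule = 1, kept = TRUE, reason = NA_character_,
                   rel_crop = list(crop), crop_shape = list(shape))
  }
  tab <- dplyr::bind_rows(mk_row(10), mk_row(1.5), mk_row(10), mk_row(10))
  out <- brightness_filter(tab)
  expect_true(out$kept[1])
  expect_false(out$kept[2])
  expect_equal(out$reason[2], "not twice as bright as environment")
  # a positive outlier far above the ensemble mean + 1 SD is discarded
  tab2 <- dplyr::bind_rows(mk_row(10), mk_row(10.5), mk_row(9.5),
                           mk_row(10), mk_row(50))
  out2 <- brightness_filter(tab2)
  expect_false(out2$kept[5])
  expect_equal(out2$reason[5], "positive outlier")
})
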