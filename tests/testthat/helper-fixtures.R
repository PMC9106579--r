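# Shared fixtures: a reduced synthetic scene for fast unit tests and a few
# hand-built image fixtures.

small_spec <- function(footprint_scale = 0.16, n_granules = 3, ...) {
  scene_spec(grid_dim = c(160L, 160L, 12L), footprint_scale = footprint_scale,
             nucleus_semi = c(7.0, 5.5, 0.8), n_granules = n_granules,
             radius_range = c(0.40, 0.85), ...)
}

# one rendered synthetic cell with chosen granules (deterministic)
one_cell <- function(spec = small_spec(photon_scale = 0), granules = NULL,
                     seed = 1) {
  set.seed(seed)
  geom <- generate_cell_geometry(spec)
  ch <- render_channels(geom, spec, granules = granules)
  stacks <- apply_optics_and_noise(ch, spec)
  list(spec = spec, geom = geom, channels = ch, stacks = stacks)
}

# run prep on a single cell with relaxed batch size
prep_one <- function(cell) {
  det <- detect_footprints(cell$stacks[c("granule", "tubulin")],
                           cell$stacks$nucleus)
  bh <- estimate_base_height(det$stacks$tubulin)
  det$z_b <- bh$z_b; det$z_peak <- bh$z_peak; det$id <- 1L
  qa <- qc_and_align(list(det),
                     area_target = scene_footprint_area(cell$spec, TRUE),
                     min_batch = 1, canvas = cell$spec$grid_dim[1:2])
  rec <- qa$records[[1]]
  rec$norm <- list(granule = normalize_channel(rec, "granule")$stack,
                   tubulin = normalize_channel(rec, "tubulin")$stack)
  rec
}

# a flat stack with solid bright spheres (index units), for detection tests
sphere_stack <- function(centres, radii, dims = c(64L, 64L, 12L),
                         bg = 1, fg = 10, noise_sd = 0.02, seed = 99) {
  set.seed(seed)
  arr <- array(bg, dims)
  for (k in seq_along(radii)) {
    cc <- centres[[k]]; R <- radii[k]
    for (z in seq_len(dims[3])) for (x in seq_len(dims[2])) for (y in seq_len(dims[1])) {
      if ((y - cc[1])^2 + (x - cc[2])^2 + (z - cc[3])^2 <= R^2)
        arr[y, x, z] <- fg
    }
  }
  arr <- arr + rnorm(length(arr), 0, noise_sd)
  channel_stack(arr, pitch_xy = 0.065, z_step = 0.2, channel = "granule")
}
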