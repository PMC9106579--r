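#' Specification of a synthetic two-channel confocal scene
#'
#' Describes a micropatterned stadium-shaped cell with an off-centre nucleus,
#' a population of stress granules with diffuse interfaces, and a tubulin
#' channel rendered either as a filament network or in depolymerized mode
#' with prescribed bulk/surface partitioning. All lengths are in micrometres.
#'
#' The default footprint is the experimental micropattern (a 25 um x 30 um
#' rectangle with two hemispherical caps of radius 12.5 um) scaled by
#' `footprint_scale` so the cell fits the default 256 x 256 grid at the
#' acquisition pixel pitch of 0.065 um. Geometric similarity preserves the
#' principal-axis ratio used by cell QC; the QC area target scales as
#' `footprint_scale^2`.
#'
#' @param grid_dim integer c(ny, nx, nz) voxel grid (default 256 x 256 x 12).
#' @param pitch_xy,z_step voxel pitch (um/px) and z spacing (um).
#' @param footprint_scale scale factor applied to the experimental pattern.
#' @param rect_length,rect_width,cap_radius stadium parameters before scaling.
#' @param nucleus_semi nucleus ellipsoid semi-axes c(long, short, z) in um
#'   (before scaling of the in-plane axes).
#' @param nucleus_offset offset of the nucleus centre along the long axis in
#'   um (negative = left hemisphere; before scaling).
#' @param base_slice first z slice inside the cell (cell base height).
#' @param n_granules mean granule count per cell (Poisson, at least 1).
#' @param radius_meanlog,radius_sdlog,radius_range log-normal radius
#'   distribution (um), truncated to `radius_range`.
#' @param frac_round fraction of granules with aspect ratio drawn below 1.5.
#' @param aspect_max maximum aspect ratio for the elongated fraction.
#' @param interface_width half-width of the granule marker's tanh intensity
#'   step, um.
#' @param interior_ratio granule interior / cytosol intensity ratio of the
#'   granule marker channel.
#' @param landscape_width half-width w of the adsorption free-energy landscape
#'   mapped onto the signed distance to the granule surface, um.
#' @param lnkg_mean,lnkg_sd,lnks_mean,lnks_sd Gaussian cohort distribution of
#'   the true bulk and surface affinities (k_BT units).
#' @param tubulin_mode `"depolymerized"` or `"filament"`.
#' @param filament_length,filament_density filament-mode segment length (um)
#'   and number of segments per cell.
#' @param cytosol_level base intensity of both channels in the cytosol (a.u.).
#' @param z_bump_amp,z_bump_sd amplitude and width (um) of the axial intensity
#'   profile peaking three slices above the cell base.
#' @param psf_sigma_xy,psf_sigma_z Gaussian PSF widths, um.
#' @param photon_scale photons per intensity unit for scaled-Poisson shot
#'   noise; 0 disables noise.
#' @param orientation_sd,orientation_max per-cell orientation jitter (deg).
#' @param centre_jitter per-cell centre jitter (um, uniform in +/-).
#' @param seed integer seed for [generate_ensemble()].
#' @return A `scene_spec` object (a validated list).
#' @export
scene_spec <- function(grid_dim = c(256L, 256L, 12L),
                       pitch_xy = 0.065, z_step = 0.200,
                       footprint_scale = 0.26,
                       rect_length = 30, rect_width = 25, cap_radius = 12.5,
                       nucleus_semi = c(7.0, 5.5, 0.8),
                       nucleus_offset = -7.5,
                       base_slice = 3L,
                       n_granules = 7,
                       radius_meanlog = log(0.72), radius_sdlog = 0.22,
                       radius_range = c(0.40, 0.90),
                       frac_round = 0.80, aspect_max = 2.2,
                       interface_width = 0.15,
                       interior_ratio = 10,
                       landscape_width = 0.26,
                       lnkg_mean = -0.016, lnkg_sd = 0.04,
                       lnks_mean = 0.066, lnks_sd = 0.015,
                       tubulin_mode = c("depolymerized", "filament"),
                       filament_length = 3.0, filament_density = 60,
                       cytosol_level = 1.0,
                       z_bump_amp = 0.25, z_bump_sd = 0.5,
                       psf_sigma_xy = 0.083, psf_sigma_z = 0.25,
                       photon_scale = 1000,
                       orientation_sd = 1.2, orientation_max = 2.8,
                       centre_jitter = 0.3,
                       seed = 1L) {
  tubulin_mode <- match.arg(tubulin_mode)
  s <- footprint_scale
  spec <- list(
    grid_dim = as.integer(grid_dim), pitch_xy = pitch_xy, z_step = z_step,
    footprint_scale = s,
    rect_length = rect_length * s, rect_width = rect_width * s,
    cap_radius = cap_radius * s,
    nucleus_semi = c(nucleus_semi[1] * s, nucleus_semi[2] * s, nucleus_semi[3]),
    nucleus_offset = nucleus_offset * s,
    base_slice = as.integer(base_slice),
    n_granules = n_granules,
    radius_meanlog = radius_meanlog, radius_sdlog = radius_sdlog,
    radius_range = radius_range,
    frac_round = frac_round, aspect_max = aspect_max,
    interface_width = interface_width, interior_ratio = interior_ratio,
    landscape_width = landscape_width,
    lnkg_mean = lnkg_mean, lnkg_sd = lnkg_sd,
    lnks_mean = lnks_mean, lnks_sd = lnks_sd,
    tubulin_mode = tubulin_mode,
    filament_length = filament_length, filament_density = filament_density,
    cytosol_level = cytosol_level,
    z_bump_amp = z_bump_amp, z_bump_sd = z_bump_sd,
    psf_sigma_xy = psf_sigma_xy, psf_sigma_z = psf_sigma_z,
    photon_scale = photon_scale,
    orientation_sd = orientation_sd, orientation_max = orientation_max,
    centre_jitter = centre_jitter,
    seed = as.integer(seed)
  )
  validate_scene_spec(spec)
  structure(spec, class = "scene_spec")
}

validate_scene_spec <- function(spec) {
  with(spec, {
    stopifnot(
      all(grid_dim >= 4), pitch_xy > 0, z_step > 0,
      rect_length > 0, rect_width > 0, cap_radius > 0,
      all(nucleus_semi > 0), base_slice >= 1,
      interface_width > 0, interior_ratio >= 0, landscape_width > 0,
      cytosol_level > 0, psf_sigma_xy >= 0, psf_sigma_z >= 0,
      photon_scale >= 0, radius_range[1] > 0,
      radius_range[2] < cap_radius
    )
    # nucleus must fit inside the stadium footprint
    half_len <- rect_length / 2 + cap_radius
    if (abs(nucleus_offset) + nucleus_semi[1] >= half_len ||
        nucleus_semi[2] >= cap_radius)
      stop("nucleus not containable in footprint")
  })
  invisible(spec)
}

#' Expected footprint area of a scene's stadium pattern
#'
#' Analytic area of the stadium (rectangle plus two hemispherical caps).
#' The experimental pattern's nominal area constant (1257 um^2) scales as the
#' square of the footprint scale when used as the QC target for synthetic
#' batches.
#'
#' @param spec a [scene_spec()].
#' @param nominal if `TRUE`, return the scaled nominal constant
#'   `1257 * footprint_scale^2` used by the QC area window; otherwise the
#'   exact analytic stadium area.
#' @return area in um^2.
#' @export
scene_footprint_area <- function(spec, nominal = FALSE) {
  if (nominal) return(1257 * spec$footprint_scale^2)
  spec$rect_length * spec$rect_width + pi * spec$cap_radius^2
}
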