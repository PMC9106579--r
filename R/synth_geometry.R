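# Analytic cell geometry for synthetic scenes.
#
# Geometry is evaluated in a rotated/offset frame so that per-cell orientation
# and centre jitter are exact (no interpolation): a voxel (x, y) in image
# coordinates maps to pattern coordinates (u, v) by rotation about the cell
# centre.

# image-plane coordinate grids in um, centred on the grid centre
grid_coords <- function(spec) {
  ny <- spec$grid_dim[1]; nx <- spec$grid_dim[2]; nz <- spec$grid_dim[3]
  x <- (seq_len(nx) - (nx + 1) / 2) * spec$pitch_xy
  y <- (seq_len(ny) - (ny + 1) / 2) * spec$pitch_xy
  z <- (seq_len(nz) - 1) * spec$z_step
  list(x = x, y = y, z = z)
}

# signed distance (um) from points (x, y) to the stadium outline;
# negative inside. Stadium: distance to the medial segment <= cap_radius.
stadium_sdf <- function(x, y, half_seg, cap_radius) {
  dx <- pmax(abs(x) - half_seg, 0)
  sqrt(dx^2 + y^2) - cap_radius
}

#' Generate the cell and nucleus geometry of a synthetic scene
#'
#' Builds the stadium-shaped cell footprint, extruded over z above the cell
#' base height, and an ellipsoidal nucleus offset into one hemisphere. The
#' cell may be rotated by `orientation` degrees and translated by `centre`
#' (um) to emulate acquisition jitter; masks are evaluated analytically in the
#' rotated frame so the geometry is exact.
#'
#' @param spec a [scene_spec()].
#' @param orientation cell long-axis orientation in degrees.
#' @param centre c(x, y) offset of the cell centre from the grid centre, um.
#' @return list with the 2D footprint mask, 2D nucleus mask, 3D in-cell mask,
#'   3D nucleus mask, base slice, orientation, centre and coordinate grids.
#' @export
generate_cell_geometry <- function(spec, orientation = 0, centre = c(0, 0)) {
  validate_scene_spec(spec)
  g <- grid_coords(spec)
  ny <- spec$grid_dim[1]; nx <- spec$grid_dim[2]; nz <- spec$grid_dim[3]
  th <- orientation * pi / 180
  X <- matrix(rep(g$x, each = ny), ny, nx)
  Y <- matrix(rep(g$y, nx), ny, nx)
  U <- cos(th) * (X - centre[1]) + sin(th) * (Y - centre[2])
  V <- -sin(th) * (X - centre[1]) + cos(th) * (Y - centre[2])
  half_seg <- spec$rect_length / 2
  cell2d <- stadium_sdf(U, V, half_seg, spec$cap_radius) <= 0
  # nucleus: ellipse in-plane, ellipsoid in 3D centred mid-cell in z
  un <- U - spec$nucleus_offset
  nuc2d <- (un / spec$nucleus_semi[1])^2 + (V / spec$nucleus_semi[2])^2 <= 1
  if (!all(cell2d[nuc2d])) stop("nucleus not containable in footprint")
  base_z <- (spec$base_slice - 1) * spec$z_step
  top_z <- g$z[nz]
  zc_nuc <- (base_z + top_z) / 2
  in_cell <- array(FALSE, c(ny, nx, nz))
  nuc3d <- array(FALSE, c(ny, nx, nz))
  for (iz in seq_len(nz)) {
    if (iz < spec$base_slice) next
    in_cell[, , iz] <- cell2d
    zz <- (g$z[iz] - zc_nuc) / spec$nucleus_semi[3]
    if (abs(zz) <= 1) {
      shrink <- sqrt(max(0, 1 - zz^2))
      if (shrink > 0) {
        nuc3d[, , iz] <- (un / (spec$nucleus_semi[1] * shrink))^2 +
          (V / (spec$nucleus_semi[2] * shrink))^2 <= 1
      }
    }
  }
  list(cell2d = cell2d, nucleus2d = nuc2d, in_cell = in_cell,
       nucleus3d = nuc3d, base_slice = spec$base_slice,
       orientation = orientation, centre = centre, coords = g,
       U = U, V = V)
}
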