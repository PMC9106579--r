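# Ensemble reference cell: expected intensity per aligned 3D location.

#' Build the ensemble reference cell for one channel
#'
#' Each aligned, normalized cell is blurred in-plane with a Gaussian kernel
#' (variance `blur_var` px^2, i.e. sigma = 2 px by default), masked by its own
#' cell and nucleus shapes, and re-sliced so slice 1 is its own base height.
#' Every cell contributes twice via folding across the long-axis centre line;
#' a voxel's reference value is the mean over unmasked contributors and is
#' valid only where more than half of the contributors are unmasked. The
#' result is mirrored back across the centre line, so the reference is exactly
#' symmetric. Validity in z is limited to the base height plus `z_range_um`.
#'
#' @param records aligned cells with normalized stacks in `$norm`.
#' @param channel channel name.
#' @param blur_var in-plane Gaussian variance, px^2.
#' @param z_range_um reliable height above the cell base, um.
#' @return A `reference_cell` object: expected-intensity array
#'   (ny, nx, n_slices), validity mask, contributor counts, average cell and
#'   nucleus shape, and metadata.
#' @export
build_reference <- function(records, channel, blur_var = 4, z_range_um = 1.2) {
  if (!length(records)) stop("empty ensemble")
  sigma <- sqrt(blur_var)
  s1 <- records[[1]]$norm[[channel]]
  canvas <- dim(s1$values)[1:2]
  z_step <- s1$z_step
  nzr <- as.integer(round(z_range_um / z_step)) + 1L
  acc <- array(0, c(canvas, nzr))
  cnt <- array(0L, c(canvas, nzr))
  shape_acc <- matrix(0, canvas[1], canvas[2])
  nuc_acc <- matrix(0, canvas[1], canvas[2])
  for (rec in records) {
    s <- rec$norm[[channel]]
    v <- stack_values(s)
    d <- dim(v)
    v <- cpp_gauss3d(v, d, sigma, sigma, 0, TRUE)
    v[is.na(stack_values(s))] <- NA # blur must not unmask voxels
    for (j in seq_len(nzr)) {
      z <- rec$z_b + j - 1L
      if (z < 1 || z > d[3]) next
      sl <- v[, , z]
      for (m in list(sl, sl[rev(seq_len(canvas[1])), ])) { # fold across centre line
        ok <- !is.na(m)
        acc[, , j] <- acc[, , j] + ifelse(ok, m, 0)
        cnt[, , j] <- cnt[, , j] + ok
      }
    }
    shape_acc <- shape_acc + rec$cell2d
    nuc_acc <- nuc_acc + rec$nucleus2d
  }
  n2 <- 2L * length(records)
  mean_arr <- ifelse(cnt > 0, acc / cnt, NA_real_)
  valid <- cnt > n2 / 2
  # mirror back across the long-axis centre line: average with the flipped
  # field (identical by construction of the folded sums, but enforce exactly)
  for (j in seq_len(nzr)) {
    m <- mean_arr[, , j]
    mean_arr[, , j] <- (m + m[rev(seq_len(canvas[1])), ]) / 2
    valid[, , j] <- valid[, , j] & valid[rev(seq_len(canvas[1])), , j]
  }
  structure(list(
    values = mean_arr, valid = valid, count = cnt,
    n_cells = length(records),
    cell_shape = shape_acc / length(records),
    nucleus_shape = nuc_acc / length(records),
    channel = channel, z_step = z_step, pitch_xy = s1$pitch_xy,
    n_slices = nzr
  ), class = "reference_cell")
}

#' @export
print.reference_cell <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<reference_cell '%s' %d x %d x %d slices, N = %d cells>\n",
              x$channel, d[1], d[2], d[3], x$n_cells))
  invisible(x)
}

#' Look up the reference crop matching a granule crop
#'
#' Returns the expected-intensity image of the reference cell at the same
#' aligned coordinates and the same height above the cell base as a granule
#' crop. Granules whose centroid plane lies outside the reference's valid
#' z-range are excluded.
#'
#' @param ref a [build_reference()] result.
#' @param record the granule's aligned cell.
#' @param origin crop origin `c(y, x, z)` from [crop_granule_images()].
#' @param size crop edge length, px.
#' @return the reference crop matrix (`NA` where invalid), or `NULL` with
#'   attribute `reason` when the granule is outside the valid z-range.
#' @export
lookup_reference <- function(ref, record, origin, size = 221L) {
  j <- origin["z"] - record$z_b + 1L
  if (is.na(j) || j < 1 || j > ref$n_slices) return(NULL)
  v <- ref$values[, , j]
  v[!ref$valid[, , j]] <- NA
  d <- dim(v)
  m <- matrix(NA_real_, size, size)
  ys <- origin["y"] + seq_len(size) - 1L
  xs <- origin["x"] + seq_len(size) - 1L
  oky <- ys >= 1 & ys <= d[1]; okx <- xs >= 1 & xs <= d[2]
  if (any(oky) && any(okx)) m[which(oky), which(okx)] <- v[ys[oky], xs[okx]]
  m
}
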